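#' Cross-validation design for the random-forest classifier
#'
#' Defaults follow the standard protocol for methylation-based disease
#' prediction: three iterations of five-fold cross-validation (15 runs, each
#' training on 80% of samples), the top 1,000 label-associated sites
#' selected per fold on training data only, and a forest of 1,000 trees with
#' `mtry = 300` candidate sites per split.
#'
#' @param n_iterations,n_folds CV repetitions and folds per repetition.
#' @param n_selected_sites Sites kept by the in-fold screening (exactly this
#'   many, for determinism).
#' @param mtry,n_trees Random-forest hyperparameters.
#' @param seed Integer seed controlling fold assignment and forest fitting.
#' @return A `cv_design` list.
#' @export
cv_design <- function(n_iterations = 3, n_folds = 5, n_selected_sites = 1000,
                      mtry = 300, n_trees = 1000, seed = 1L) {
  if (n_folds < 2) abort("n_folds must be >= 2")
  if (n_iterations < 1) abort("n_iterations must be >= 1")
  if (n_selected_sites < 1) abort("n_selected_sites must be >= 1")
  structure(list(n_iterations = as.integer(n_iterations),
                 n_folds = as.integer(n_folds),
                 n_selected_sites = as.integer(n_selected_sites),
                 mtry = as.integer(mtry), n_trees = as.integer(n_trees),
                 seed = as.integer(seed)),
            class = "cv_design")
}

#' Screen sites by association with a binary label (training data only)
#'
#' Per-site simple linear regression of beta on the binary label, ranked by
#' p-value ascending with deterministic tie-breaking (larger |coefficient|
#' first, then site id lexicographically). In the cross-validation protocol
#' this runs once per fold on the training folds only, so held-out samples
#' never influence which sites the forest sees.
#'
#' @param beta_train A [beta_matrix()] restricted to training samples.
#' @param labels_train Binary vector (0/1 or logical), one per training
#'   sample.
#' @param k Number of sites to return (`<=` number of sites).
#' @return Character vector of exactly `k` site ids.
#' @export
select_features_on_training <- function(beta_train, labels_train, k) {
  y <- as.numeric(labels_train)
  if (length(unique(y)) < 2) abort("labels are constant; screening undefined")
  if (k > nrow(beta_train)) abort("k exceeds the number of sites")
  X <- cbind(`(Intercept)` = 1, case = y)
  fit <- ols_many(X, t(unclass(beta_train)), coef_name = "case")
  ord <- order(fit$p, -abs(fit$coef), rownames(beta_train))
  rownames(beta_train)[ord][seq_len(k)]
}

#' Nested cross-validated random-forest prediction of disease status
#'
#' For each iteration, samples are partitioned into class-stratified folds
#' from an iteration-derived seed. For each fold, site screening
#' ([select_features_on_training()]) and forest fitting use the training
#' folds only; the held-out fold receives out-of-fold case probabilities
#' (the fraction of trees voting case). Each sample is predicted exactly
#' once per iteration; AUC is computed per iteration on the pooled
#' out-of-fold predictions and averaged across iterations.
#'
#' The `feature_selection = "global"` mode deliberately breaks the leakage
#' contract by screening once on the full data set before cross-validation;
#' it exists only to demonstrate the optimistic bias that in-fold screening
#' prevents.
#'
#' @param beta A [beta_matrix()].
#' @param sheet Sample sheet.
#' @param group_case,group_control Group labels to classify.
#' @param design A [cv_design()].
#' @param serology_filter Optional `"positive"`/`"negative"`: restrict the
#'   case group to that serology subgroup before splitting.
#' @param feature_selection `"in_fold"` (leakage-safe, default) or
#'   `"global"`.
#' @return A `prediction_result` list: `predictions` (tibble: `iteration`,
#'   `fold`, `sample_id`, `label`, `score`), `auc_by_iteration`, `mean_auc`,
#'   `pooled_auc`, `comparison`, `design`.
#' @export
crossval_predict <- function(beta, sheet, group_case, group_control,
                             design = cv_design(), serology_filter = NULL,
                             feature_selection = c("in_fold", "global")) {
  feature_selection <- match.arg(feature_selection)
  sheet <- validate_sample_sheet(sheet)
  keep <- sheet$group %in% c(group_case, group_control)
  if (!is.null(serology_filter)) {
    keep <- keep & (sheet$group != group_case | sheet$serology == serology_filter)
  }
  sub <- sheet[keep, ]
  y <- factor(ifelse(sub$group == group_case, "case", "control"),
              levels = c("control", "case"))
  if (min(table(y)) < design$n_folds) {
    abort(sprintf("smallest class has %d samples; need >= n_folds = %d",
                  min(table(y)), design$n_folds))
  }
  B <- unclass(beta)[, sub$sample_id, drop = FALSE]
  k <- min(design$n_selected_sites, nrow(B))

  global_sites <- NULL
  if (feature_selection == "global") {
    global_sites <- select_features_on_training(
      beta_matrix(B), as.numeric(y == "case"), k
    )
  }

  predictions <- purrr::map_dfr(seq_len(design$n_iterations), function(it) {
    withr::with_seed(design$seed + 10007L * it, {
      fold <- stratified_folds(y, design$n_folds)
      purrr::map_dfr(seq_len(design$n_folds), function(f) {
        train <- fold != f
        sites <- global_sites %||% select_features_on_training(
          beta_matrix(B[, train, drop = FALSE]),
          as.numeric(y[train] == "case"), k
        )
        rf <- randomForest::randomForest(
          x = t(B[sites, train, drop = FALSE]), y = y[train],
          ntree = design$n_trees, mtry = min(design$mtry, length(sites))
        )
        score <- predict(rf, t(B[sites, !train, drop = FALSE]),
                         type = "prob")[, "case"]
        tibble(iteration = it, fold = f,
               sample_id = sub$sample_id[!train],
               label = as.character(y[!train]), score = unname(score))
      })
    })
  })

  auc_by_iteration <- predictions |>
    group_by(.data$iteration) |>
    summarise(auc = roc_auc(.data$score, .data$label == "case")$auc,
              .groups = "drop")
  structure(list(
    predictions = predictions,
    auc_by_iteration = auc_by_iteration,
    mean_auc = mean(auc_by_iteration$auc),
    pooled_auc = roc_auc(predictions$score, predictions$label == "case")$auc,
    comparison = paste0(group_case,
                        if (!is.null(serology_filter)) paste0("[", serology_filter, "]"),
                        " vs ", group_control),
    design = design
  ), class = "prediction_result")
}

# class-stratified fold assignment: shuffle within class, deal round-robin
stratified_folds <- function(y, n_folds) {
  fold <- integer(length(y))
  for (cl in levels(y)) {
    idx <- sample(which(y == cl))
    fold[idx] <- rep_len(seq_len(n_folds), length(idx))
  }
  fold
}

#' @export
print.prediction_result <- function(x, ...) {
  cat(sprintf("<prediction_result> %s\n", x$comparison))
  cat(sprintf("  mean AUC over %d iterations: %.3f (pooled %.3f)\n",
              nrow(x$auc_by_iteration), x$mean_auc, x$pooled_auc))
  invisible(x)
}

#' ROC curve and AUC by pair counting
#'
#' The AUC is the Mann-Whitney pair-counting statistic: the fraction of
#' (case, control) pairs in which the case scores higher, with ties counting
#' one half. ROC points are reported at every threshold step.
#'
#' @param scores Numeric prediction scores (higher = more case-like).
#' @param labels Binary labels: logical, 0/1, or a vector equal to
#'   `case_label` for cases.
#' @param case_label Value of `labels` identifying cases (default `TRUE`).
#' @return List: `auc` (scalar) and `roc` (tibble `threshold`, `fpr`, `tpr`
#'   including the (0,0) and (1,1) endpoints).
#' @export
roc_auc <- function(scores, labels, case_label = TRUE) {
  is_case <- if (is.logical(labels)) labels else labels == case_label
  n1 <- sum(is_case); n0 <- sum(!is_case)
  if (n1 == 0 || n0 == 0) abort("both classes must be present")
  r <- rank(scores)  # midranks: ties contribute 0.5 per pair
  auc <- (sum(r[is_case]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  thr <- sort(unique(scores), decreasing = TRUE)
  tpr <- vapply(thr, function(t) sum(scores >= t & is_case) / n1, numeric(1))
  fpr <- vapply(thr, function(t) sum(scores >= t & !is_case) / n0, numeric(1))
  roc <- tibble(threshold = c(Inf, thr), fpr = c(0, fpr), tpr = c(0, tpr))
  if (roc$fpr[nrow(roc)] < 1 || roc$tpr[nrow(roc)] < 1) {
    roc <- bind_rows(roc, tibble(threshold = -Inf, fpr = 1, tpr = 1))
  }
  list(auc = auc, roc = roc)
}
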