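#' Bonferroni significance threshold
#'
#' Returns `alpha / n_tests` exactly; no rounding happens internally.
#' Rounding to two significant figures is applied only when a threshold is
#' displayed in reports (see [format_threshold()]), e.g. 0.05 over 385,962
#' tested sites prints as `1.3 x 10^-7`.
#'
#' @param alpha Family-wise significance level in (0, 1).
#' @param n_tests Number of tests (>= 1).
#' @return The exact per-test p-value cutoff.
#' @examples
#' bonferroni_threshold(0.05, 385962)
#' format_threshold(bonferroni_threshold(0.05, 7625))
#' @export
bonferroni_threshold <- function(alpha = 0.05, n_tests) {
  if (alpha <= 0 || alpha >= 1) abort("alpha must be in (0, 1)")
  if (n_tests < 1) abort("n_tests must be >= 1")
  alpha / n_tests
}

#' @rdname bonferroni_threshold
#' @param cutoff A p-value cutoff to display.
#' @return `format_threshold()`: the cutoff rounded to 2 significant figures
#'   in the conventional `m x 10^e` notation.
#' @export
format_threshold <- function(cutoff) {
  vapply(cutoff, function(x) {
    if (x == 0) return("0")
    e <- floor(log10(abs(x)))
    m <- signif(x / 10^e, 2)
    if (abs(m) >= 10) { m <- m / 10; e <- e + 1 }
    if (e == 0) format(m) else sprintf("%s × 10^%d", format(m), e)
  }, character(1))
}

#' Fit the per-site covariate-adjusted linear model
#'
#' Ordinary least squares of a site's beta-values on a case indicator plus
#' covariates; the reported p-value is the two-sided t-test on the case
#' coefficient with `n - k` residual degrees of freedom. When the residual
#' variance is exactly zero the fit is degenerate: a zero case coefficient
#' is reported with p = 1 (so null fixtures stay runnable), anything else is
#' an error.
#'
#' @param y Numeric vector of beta-values, one per sample.
#' @param design Data frame of covariates including a numeric `case`
#'   indicator column (0/1); an intercept is added. Alternatively a numeric
#'   model matrix with a `case` column.
#' @return One-row tibble: `coefficient`, `se`, `p`, `df`.
#' @export
fit_site_model <- function(y, design) {
  X <- if (is.matrix(design)) design else
    stats::model.matrix(~ ., data = as.data.frame(design))
  if (!"case" %in% colnames(X)) abort("design must contain a `case` indicator column")
  if (nrow(X) != length(y)) abort("design rows must match length(y)")
  fit <- ols_many(X, matrix(y, ncol = 1), coef_name = "case")
  tibble(coefficient = fit$coef, se = fit$se, p = fit$p, df = fit$df)
}

# vectorised OLS across sites: X n x k, Y n x p; t-test on one coefficient
ols_many <- function(X, Y, coef_name = "case") {
  n <- nrow(X); k <- ncol(X)
  if (n <= k) abort(sprintf("too few samples for the model: n = %d, k = %d", n, k))
  qx <- qr(X)
  if (qx$rank < k) {
    abort(paste0("rank-deficient design; involved column(s): ",
                 paste(colnames(X)[qx$pivot[-seq_len(qx$rank)]], collapse = ", ")))
  }
  coefs <- qr.coef(qx, Y)                       # k x p
  resid <- Y - X %*% coefs
  df <- n - k
  sigma2 <- colSums(resid^2) / df
  XtX_inv <- chol2inv(qr.R(qx))[order(qx$pivot), order(qx$pivot), drop = FALSE]
  j <- match(coef_name, colnames(X))
  cjj <- XtX_inv[j, j]
  b <- coefs[j, ]
  se <- sqrt(pmax(sigma2 * cjj, 0))
  degen <- sigma2 < 1e-24
  if (any(degen & abs(b) > 1e-10)) {
    abort("degenerate perfect fit: zero residual variance with a nonzero case coefficient")
  }
  tval <- ifelse(se > 0, b / se, 0)
  p <- 2 * pt(-abs(tval), df)
  p[degen] <- 1
  p <- pmax(pmin(p, 1), 1e-300)                 # keep p in (0, 1]
  list(coef = unname(b), se = unname(se), p = unname(p), df = df)
}

#' Run a covariate-adjusted EWAS between two groups
#'
#' Fits, per CpG site, a linear regression of methylation on a case-status
#' indicator with sex, age and (when supplied) estimated blood cell-type
#' proportions as covariates, over the samples of the two compared groups
#' only. Significance comes from the adjusted model; the reported
#' `delta_beta` is the difference of raw group means
#' (`mean(case) - mean(reference)`), deliberately decoupled from the
#' adjusted coefficient.
#'
#' @param beta A [beta_matrix()].
#' @param sheet Sample sheet covering the beta matrix samples.
#' @param case_group,reference_group Group labels to compare (must differ).
#' @param proportions Optional `cell_proportions` from
#'   [estimate_proportions()]; all cell-type columns enter the model (the
#'   sum-<=-1 constraint keeps the design full rank).
#' @param covariates Character vector among `"sex"`, `"age"`.
#' @param use_m_values If `TRUE`, fit on `log2(beta / (1 - beta))` (M-values)
#'   instead of beta; group means and `delta_beta` stay on the beta scale.
#' @param serology_filter Optional `"positive"`/`"negative"`: restrict a
#'   `disease_B` case group to that serology subgroup.
#' @return An `ewas_result` tibble with one row per site: `site_id`,
#'   `coefficient`, `se`, `p`, `mean_case`, `mean_reference`, `delta_beta`,
#'   `n`. Attributes record the comparison and model.
#' @export
run_ewas <- function(beta, sheet, case_group, reference_group,
                     proportions = NULL, covariates = c("sex", "age"),
                     use_m_values = FALSE, serology_filter = NULL) {
  if (identical(case_group, reference_group)) {
    abort("case and reference group must differ")
  }
  sheet <- validate_sample_sheet(sheet)
  keep <- sheet$group %in% c(case_group, reference_group)
  if (!is.null(serology_filter)) {
    keep <- keep & (sheet$group != case_group | sheet$serology == serology_filter)
  }
  sub <- sheet[keep, ]
  if (!any(sub$group == case_group)) abort(paste0("no samples in case group ", case_group))
  if (!any(sub$group == reference_group)) abort(paste0("no samples in reference group ", reference_group))
  missing_samples <- setdiff(sub$sample_id, sample_ids(beta))
  if (length(missing_samples) > 0) {
    abort(paste0("sheet sample(s) absent from beta matrix: ",
                 paste(head(missing_samples, 5), collapse = ", ")))
  }
  B <- unclass(beta)[, sub$sample_id, drop = FALSE]
  case <- as.numeric(sub$group == case_group)

  X <- cbind(`(Intercept)` = 1, case = case)
  if ("sex" %in% covariates) X <- cbind(X, sexM = as.numeric(sub$sex == "M"))
  if ("age" %in% covariates) X <- cbind(X, age = sub$age)
  if (!is.null(proportions)) {
    pr <- as_tibble(proportions)
    idx <- match(sub$sample_id, pr$sample_id)
    if (anyNA(idx)) abort("proportions missing for some modelled samples")
    W <- as.matrix(pr[idx, cell_type_columns(pr), drop = FALSE])
    X <- cbind(X, W)
  }

  # covariates that do not vary in the modelled subset (e.g. a single-sex
  # subgroup) carry no information and would only break the rank check
  keep_col <- c(TRUE, TRUE, vapply(seq_len(ncol(X) - 2), function(j) {
    var(X[, j + 2]) > 0
  }, logical(1)))
  dropped <- colnames(X)[!keep_col]
  X <- X[, keep_col, drop = FALSE]

  Y <- t(B)
  if (use_m_values) {
    eps <- 1e-6
    Y <- log2(pmin(pmax(Y, eps), 1 - eps) / (1 - pmin(pmax(Y, eps), 1 - eps)))
  }
  fit <- ols_many(X, Y, coef_name = "case")
  mean_case <- unname(rowMeans(B[, case == 1, drop = FALSE]))
  mean_ref <- unname(rowMeans(B[, case == 0, drop = FALSE]))
  out <- tibble(
    site_id = rownames(B),
    coefficient = fit$coef, se = fit$se, p = fit$p,
    mean_case = mean_case, mean_reference = mean_ref,
    delta_beta = mean_case - mean_ref,
    n = nrow(X)
  )
  structure(out,
            case_group = case_group, reference_group = reference_group,
            n_case = sum(case == 1), n_reference = sum(case == 0),
            covariates = covariates,
            dropped_covariates = dropped,
            cell_adjusted = !is.null(proportions),
            model_scale = if (use_m_values) "M" else "beta",
            serology_filter = serology_filter,
            class = c("ewas_result", class(out)))
}

#' Call differentially methylated CpG sites (DMCs)
#'
#' A site is a DMC when `p < p_cutoff` and `|delta_beta| > delta_cutoff`,
#' both inequalities strict. Direction is `hypo` for negative `delta_beta`
#' (lower methylation in the case group) and `hyper` otherwise; a site with
#' `delta_beta == 0` can never pass.
#'
#' @param result An `ewas_result`.
#' @param p_cutoff p-value cutoff, typically
#'   `bonferroni_threshold(0.05, nrow(result))`.
#' @param delta_cutoff Cutoff on `|delta_beta|` (default 0.05).
#' @return A `dmc_set` tibble: the significant rows plus a `direction`
#'   column; the thresholds used are stored as attributes `p_cutoff` and
#'   `delta_cutoff`, along with `n_tested`.
#' @export
call_dmcs <- function(result,
                      p_cutoff = bonferroni_threshold(0.05, nrow(result)),
                      delta_cutoff = 0.05) {
  if (p_cutoff <= 0 || p_cutoff >= 1) abort("p_cutoff must be in (0, 1)")
  if (delta_cutoff < 0 || delta_cutoff >= 1) abort("delta_cutoff must be in [0, 1)")
  out <- as_tibble(result) |>
    filter(.data$p < p_cutoff, abs(.data$delta_beta) > delta_cutoff) |>
    mutate(direction = ifelse(.data$delta_beta < 0, "hypo", "hyper"))
  structure(out,
            p_cutoff = p_cutoff, delta_cutoff = delta_cutoff,
            n_tested = nrow(result),
            case_group = attr(result, "case_group"),
            reference_group = attr(result, "reference_group"),
            class = c("dmc_set", class(out)))
}
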