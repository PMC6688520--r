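# shared fixtures and independent oracles, all built in code

tiny_beta <- function() {
  beta_matrix(matrix(
    c(0.10, 0.20, 0.30, 0.40, 0.50, 0.60),
    nrow = 3, byrow = TRUE,
    dimnames = list(c("cg01", "cg02", "cg03"), c("s1", "s2"))
  ))
}

tiny_sheet <- function(n_control = 4, n_A = 4, n_B = 4, seed = 11) {
  withr::with_seed(seed, {
    n <- n_control + n_A + n_B
    group <- rep(c("control", "disease_A", "disease_B"), c(n_control, n_A, n_B))
    tibble::tibble(
      sample_id = sprintf("s%02d", seq_len(n)),
      group = group,
      sex = sample(c("F", "M"), n, replace = TRUE),
      age = round(runif(n, 25, 70), 1),
      serology = replace(
        rep("not_applicable", n),
        group == "disease_B",
        c(rep("positive", ceiling(0.75 * n_B)),
          rep("negative", n_B - ceiling(0.75 * n_B)))
      )
    )
  })
}

# medium simulated cohort shared across test files (built once per run)
.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

medium_cohort <- function() {
  cached("medium_cohort", {
    design <- simulation_design(
      n_sites = 4000, n_shared = 80, n_unique_A = 40, n_unique_B = 20,
      n_module_sites = 12, seed = 421L
    )
    sim <- simulate_cohort(design)
    sim$proportions <- estimate_proportions(sim$beta, sim$reference)
    sim$design <- design
    sim
  })
}

# closed-form OLS oracle via normal equations
ols_oracle <- function(X, y, j) {
  XtX_inv <- solve(t(X) %*% X)
  bhat <- XtX_inv %*% t(X) %*% y
  resid <- y - X %*% bhat
  df <- nrow(X) - ncol(X)
  s2 <- sum(resid^2) / df
  se <- sqrt(s2 * XtX_inv[j, j])
  tval <- bhat[j] / se
  list(coef = bhat[j], se = se, p = 2 * pt(-abs(tval), df))
}

# brute-force pair-counting AUC
auc_bruteforce <- function(scores, is_case) {
  cs <- scores[is_case]; ct <- scores[!is_case]
  total <- 0
  for (a in cs) for (b in ct) total <- total + (a > b) + 0.5 * (a == b)
  total / (length(cs) * length(ct))
}

# trapezoidal integral of an ROC curve
auc_trapezoid <- function(roc) {
  o <- order(roc$fpr, roc$tpr)
  fpr <- roc$fpr[o]; tpr <- roc$tpr[o]
  sum(diff(fpr) * (head(tpr, -1) + tail(tpr, -1)) / 2)
}

# mean silhouette width over Euclidean distances (direct definition)
silhouette_mean <- function(coords, labels) {
  d <- as.matrix(dist(coords))
  sil <- vapply(seq_len(nrow(d)), function(i) {
    own <- labels == labels[i]; own[i] <- FALSE
    a <- mean(d[i, own])
    b <- min(vapply(setdiff(unique(labels), labels[i]),
                    function(l) mean(d[i, labels == l]), numeric(1)))
    (b - a) / max(a, b)
  }, numeric(1))
  mean(sil)
}

# constrained LS objective for deconvolution candidates
deconv_objective <- function(R, y, w) sum((y - R %*% w)^2)

# exhaustive simplex grid (sum(w) <= 1) at the given step, as a matrix
simplex_grid <- function(k, step) {
  stopifnot(k %in% c(2, 3))
  s <- seq(0, 1, by = step)
  if (k == 2) {
    g <- expand.grid(w1 = s, w2 = s)
  } else {
    g <- expand.grid(w1 = s, w2 = s, w3 = s)
  }
  as.matrix(g[rowSums(g) <= 1 + 1e-12, , drop = FALSE])
}
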