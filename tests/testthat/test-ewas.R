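test_that("Bonferroni thresholds are exact and display to 2 significant figures", {
  expect_identical(bonferroni_threshold(0.05, 1), 0.05)
  expect_equal(bonferroni_threshold(0.05, 385962), 0.05 / 385962)
  expect_identical(format_threshold(bonferroni_threshold(0.05, 385962)), "1.3 × 10^-7")
  expect_identical(format_threshold(bonferroni_threshold(0.05, 7625)), "6.6 × 10^-6")
  expect_error(bonferroni_threshold(1.5, 10), "alpha")
})

test_that("the site model matches the closed-form normal-equations oracle", {
  # worked 6-point instance
  y <- c(0.21, 0.25, 0.23, 0.40, 0.44, 0.38)
  design <- data.frame(case = c(0, 0, 0, 1, 1, 1),
                       age = c(30, 45, 50, 35, 42, 60))
  fit <- fit_site_model(y, design)
  X <- cbind(1, case = design$case, age = design$age)
  oracle <- ols_oracle(X, y, 2)
  expect_equal(fit$coefficient, oracle$coef, tolerance = 1e-10)
  expect_equal(fit$se, oracle$se, tolerance = 1e-10)
  expect_equal(fit$p, oracle$p, tolerance = 1e-10)

  # property: 100 random instances
  withr::with_seed(51, {
    for (i in 1:100) {
      n <- sample(8:30, 1)
      X <- cbind(1, case = rbinom(n, 1, 0.5), x1 = rnorm(n), x2 = runif(n))
      if (length(unique(X[, "case"])) < 2) next
      y <- runif(n)
      fit <- fit_site_model(y, X)
      oracle <- ols_oracle(X, y, 2)
      expect_equal(fit$coefficient, oracle$coef, tolerance = 1e-10)
      expect_equal(fit$p, oracle$p, tolerance = 1e-10)
    }
  })
})

test_that("degenerate fits are guarded", {
  y <- rep(0.4, 8)
  design <- data.frame(case = rep(c(0, 1), each = 4))
  fit <- fit_site_model(y, design)
  expect_equal(fit$coefficient, 0)
  expect_equal(fit$p, 1)

  # perfect separation with zero residual variance is an error
  y2 <- rep(c(0.2, 0.8), each = 4)
  expect_error(fit_site_model(y2, design), "degenerate")

  expect_error(fit_site_model(runif(3), data.frame(case = c(0, 1, 1),
                                                   a = 1:3, b = 3:1, c = c(1, 2, 4))),
               "too few samples")
  expect_error(fit_site_model(runif(8), data.frame(case = rep(0:1, 4),
                                                   dup = rep(0:1, 4))),
               "rank-deficient")
})

test_that("t-test p agrees with a permutation oracle on a null instance", {
  set.seed(61)
  y <- rnorm(20, 0.5, 0.05)
  case <- rep(c(0, 1), each = 10)
  p_t <- fit_site_model(y, data.frame(case = case))$p
  obs <- abs(mean(y[case == 1]) - mean(y[case == 0]))
  perm <- replicate(10000, {
    s <- sample(case)
    abs(mean(y[s == 1]) - mean(y[s == 0]))
  })
  p_perm <- mean(perm >= obs - 1e-15)
  expect_equal(p_t, p_perm, tolerance = 0.03)
})

test_that("run_ewas is calibrated on nulls and powered on strong effects", {
  d <- simulation_design(n_sites = 3000, n_shared = 0, n_unique_A = 0,
                         n_unique_B = 0, n_module_sites = 0,
                         n_control = 40, n_A = 40, n_B = 4,
                         confound_strength = 0, seed = 67)
  sim <- simulate_cohort(d)
  ew <- run_ewas(sim$beta, sim$sheet, "disease_A", "control")
  frac <- mean(ew$p < 0.05)
  halfwidth <- 2.576 * sqrt(0.05 * 0.95 / nrow(ew))
  expect_lt(abs(frac - 0.05), halfwidth)

  dp <- simulation_design(n_sites = 1000, n_shared = 50, n_unique_A = 0,
                          n_unique_B = 0, n_module_sites = 0,
                          n_control = 40, n_A = 40, n_B = 4,
                          delta_A = 0.25, delta_B = 0.14, precision = 800,
                          confound_strength = 0, seed = 71)
  simp <- simulate_cohort(dp)
  ewp <- run_ewas(simp$beta, simp$sheet, "disease_A", "control")
  planted <- simp$truth$site_id[simp$truth$class == "shared"]
  expect_true(all(ewp$p[match(planted, ewp$site_id)] < 1e-7))

  expect_error(run_ewas(sim$beta, sim$sheet, "control", "control"), "must differ")
})

test_that("relabelling case and reference flips delta and keeps p", {
  sim <- medium_cohort()
  a <- run_ewas(sim$beta, sim$sheet, "disease_A", "control", sim$proportions)
  b <- run_ewas(sim$beta, sim$sheet, "control", "disease_A", sim$proportions)
  expect_equal(a$p, b$p, tolerance = 1e-12)
  expect_equal(a$delta_beta, -b$delta_beta, tolerance = 1e-12)
  expect_equal(a$coefficient, -b$coefficient, tolerance = 1e-12)
})

test_that("adjusted EWAS agrees with the limma ordinary t oracle", {
  skip_if_not_installed("limma")
  sim <- medium_cohort()
  sub <- sim$sheet[sim$sheet$group %in% c("control", "disease_A"), ]
  pr <- tibble::as_tibble(sim$proportions)
  pr <- pr[match(sub$sample_id, pr$sample_id), ]
  X <- cbind(1, case = as.numeric(sub$group == "disease_A"),
             sexM = as.numeric(sub$sex == "M"), age = sub$age,
             as.matrix(pr[, -1]))
  fit <- limma::lmFit(unclass(sim$beta)[, sub$sample_id], X)
  t_ord <- fit$coefficients[, "case"] / (fit$stdev.unscaled[, "case"] * fit$sigma)
  p_ord <- 2 * pt(-abs(t_ord), fit$df.residual)
  ew <- run_ewas(sim$beta, sim$sheet, "disease_A", "control", sim$proportions)
  expect_equal(unname(fit$coefficients[, "case"]), ew$coefficient, tolerance = 1e-8)
  expect_equal(unname(p_ord), ew$p, tolerance = 1e-8)
})

test_that("DMC calling applies strict dual thresholds and is idempotent", {
  res <- structure(
    tibble::tibble(
      site_id = c("a", "b", "c", "d", "e"),
      coefficient = 0, se = 0.1,
      p = c(1e-9, 1e-9, 1e-9, 0.5, 1e-9),
      mean_case = 0.5, mean_reference = 0.5,
      delta_beta = c(0.04, -0.06, 0.05, 0.3, 0),
      n = 80
    ),
    class = c("ewas_result", class(tibble::tibble()))
  )
  dm <- call_dmcs(res, p_cutoff = 1e-7, delta_cutoff = 0.05)
  expect_identical(dm$site_id, "b")            # |0.04| fails, |0.05| not strict, 0 never
  expect_identical(dm$direction, "hypo")
  dm2 <- call_dmcs(call_dmcs(res, 1e-7, 0.05), 1e-7, 0.05)
  expect_identical(dm2$site_id, dm$site_id)
  expect_identical(attr(dm, "p_cutoff"), 1e-7)

  # recovery on a planted cohort
  d <- simulation_design(n_sites = 3000, n_shared = 100, n_unique_A = 0,
                         n_unique_B = 0, n_module_sites = 0,
                         n_control = 40, n_A = 40, n_B = 4,
                         delta_A = 0.2, precision = 400,
                         confound_strength = 0, seed = 73)
  sim <- simulate_cohort(d)
  ew <- run_ewas(sim$beta, sim$sheet, "disease_A", "control")
  dm <- call_dmcs(ew)
  conf <- truth_confusion(dm, sim$truth, "shared")
  expect_gte(conf$sensitivity, 0.95)
  expect_lt(conf$fdp, 0.05)
})
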