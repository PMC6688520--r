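fake_ewas <- function(site_id, p, delta) {
  structure(
    tibble::tibble(site_id = site_id, coefficient = delta, se = 0.01, p = p,
                   mean_case = 0.5 + delta / 2, mean_reference = 0.5 - delta / 2,
                   delta_beta = delta, n = 80),
    class = c("ewas_result", class(tibble::tibble()))
  )
}

test_that("sharing requires the derived cutoff and a concordant direction", {
  own <- call_dmcs(fake_ewas(c("a", "b", "c"), c(1e-10, 1e-10, 1e-10),
                             c(-0.2, -0.2, 0.1)), 1e-7, 0.05)
  other <- fake_ewas(c("a", "b", "c"), c(1e-7, 0.01, 1e-8), c(0.1, -0.1, 0.2))
  shared <- classify_shared(own, other, shared_p_cutoff = 6.6e-6)
  # a: direction conflict; b: fails p; c: concordant and significant
  expect_identical(shared$site_id, "c")

  expect_error(
    classify_shared(own, other[other$site_id != "a", ], 6.6e-6),
    "universes differ"
  )
})

test_that("uniqueness requires p > 0.05 in the other EWAS, strictly", {
  own <- call_dmcs(fake_ewas(c("a", "b"), c(1e-10, 1e-10), c(-0.2, -0.2)), 1e-7, 0.05)
  other <- fake_ewas(c("a", "b"), c(0.04, 0.50), c(0, 0))
  uni <- classify_unique(own, other)
  expect_identical(uni$site_id, "b")
})

test_that("combined shared sets merge with provenance, commutatively and idempotently", {
  a <- tibble::tibble(site_id = c("s1", "s2", "s3"), p_own = 1e-9, delta_own = -0.1)
  b <- tibble::tibble(site_id = c("s3", "s4"), p_own = 1e-8, delta_own = -0.2)
  u <- combine_shared_sets(a, b)
  expect_equal(nrow(u), 4)
  expect_identical(u$provenance[u$site_id == "s3"], "both")
  expect_identical(u$provenance[u$site_id == "s1"], "from_A_dmcs")
  expect_identical(u$provenance[u$site_id == "s4"], "from_B_dmcs")

  expect_setequal(combine_shared_sets(b, a)$site_id, u$site_id)
  expect_equal(nrow(combine_shared_sets(a, a)), nrow(a))
  expect_true(all(combine_shared_sets(a, a)$provenance == "both"))

  # union arithmetic at the published set sizes: 4,725 + 572 - 352 overlap
  big_a <- tibble::tibble(site_id = sprintf("cg%05d", 1:4725))
  big_b <- tibble::tibble(site_id = sprintf("cg%05d", (4725 - 352 + 1):(4725 + 220)))
  expect_equal(nrow(combine_shared_sets(big_a, big_b)), 4945)
})

test_that("direction summaries reproduce printed integer percentages", {
  mk <- function(n_hypo, n) {
    tibble::tibble(delta_beta = c(rep(-0.1, n_hypo), rep(0.1, n - n_hypo)))
  }
  expect_equal(summarize_directions(mk(3572, 4945))$pct_hypo, 72)
  expect_equal(summarize_directions(mk(2002, 2244))$pct_hypo, 89)
  expect_equal(summarize_directions(mk(1, 2))$pct_hypo, 50)
  empty <- summarize_directions(mk(0, 0))
  expect_equal(empty$n, 0L)
  expect_true(is.na(empty$pct_hypo))
})

test_that("the full partition recovers planted classes and stays disjoint", {
  sim <- medium_cohort()
  ewA <- run_ewas(sim$beta, sim$sheet, "disease_A", "control", sim$proportions)
  ewB <- run_ewas(sim$beta, sim$sheet, "disease_B", "control", sim$proportions)
  cross <- classify_cross_disease(ewA, ewB)

  conf_shared <- truth_confusion(cross$shared, sim$truth, c("shared", "module"))
  expect_gte(conf_shared$sensitivity, 0.9)
  expect_lt(conf_shared$fdp, 0.05)

  conf_uA <- truth_confusion(cross$unique_A, sim$truth, "unique_A")
  expect_gte(conf_uA$sensitivity, 0.8)
  expect_equal(conf_uA$fp, 0)

  # no planted shared site may be labelled unique
  shared_truth <- sim$truth$site_id[sim$truth$class == "shared"]
  expect_length(intersect(cross$unique_A$site_id, shared_truth), 0)
  expect_length(intersect(cross$unique_B$site_id, shared_truth), 0)

  # shared and unique are disjoint within each disease
  expect_length(intersect(cross$shared_from_A$site_id, cross$unique_A$site_id), 0)
  expect_length(intersect(cross$shared_from_B$site_id, cross$unique_B$site_id), 0)

  # every DMC gets exactly one label and percentages recompute from counts
  expect_setequal(cross$labels_A$site_id, cross$dmcs_A$site_id)
  expect_false(any(duplicated(cross$labels_A$site_id)))
  dirs <- summarize_directions(cross$shared)
  expect_equal(dirs$pct_hypo, round(100 * dirs$n_hypo / dirs$n))
})

test_that("classify_shared is symmetric under disease swap at a common cutoff", {
  sim <- medium_cohort()
  ewA <- run_ewas(sim$beta, sim$sheet, "disease_A", "control", sim$proportions)
  ewB <- run_ewas(sim$beta, sim$sheet, "disease_B", "control", sim$proportions)
  cutoff <- 1e-4
  dmA <- call_dmcs(ewA); dmB <- call_dmcs(ewB)
  both <- intersect(dmA$site_id, dmB$site_id)
  sAB <- classify_shared(dmA, ewB, cutoff)
  sBA <- classify_shared(dmB, ewA, cutoff)
  # restricted to sites that are DMCs in both diseases, sharing is symmetric
  expect_setequal(intersect(sAB$site_id, both), intersect(sBA$site_id, both))
})

test_that("the case-case comparison flags intermediate shared effects", {
  d <- simulation_design(n_sites = 2500, n_shared = 60, n_unique_A = 0,
                         n_unique_B = 0, n_module_sites = 0,
                         n_control = 40, n_A = 35, n_B = 20,
                         delta_A = 0.2, delta_B = 0.1, frac_hypo = 1,
                         precision = 400, confound_strength = 0, seed = 83)
  sim <- simulate_cohort(d)
  pr <- estimate_proportions(sim$beta, sim$reference)
  ewA <- run_ewas(sim$beta, sim$sheet, "disease_A", "control", pr)
  ewB <- run_ewas(sim$beta, sim$sheet, "disease_B", "control", pr)
  cc <- case_case_comparison(sim$beta, sim$sheet, pr,
                             dmcs_A = call_dmcs(ewA), dmcs_B = call_dmcs(ewB))
  shared_sites <- sim$truth$site_id[sim$truth$class == "shared"]
  hit <- cc$dmcs[cc$dmcs$site_id %in% shared_sites, ]
  # hypomethylation is deeper in disease A, so delta(A - B) < 0 at planted sites
  expect_gt(nrow(hit), 0.8 * length(shared_sites))
  expect_true(all(hit$delta_beta < 0))
  expect_true(!is.null(cc$overlap))
  expect_equal(cc$overlap$pct_in_both,
               round(100 * cc$overlap$n_in_both_case_control / cc$overlap$n_case_case))
})
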