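test_that("classical MDS preserves distances on intrinsically 2-D data", {
  # 4 samples on a rectangle in a 5-site space: distances are exactly 2-D
  pts <- rbind(c(0, 0), c(0.3, 0), c(0, 0.2), c(0.3, 0.2))
  basis <- qr.Q(qr(matrix(c(1, 0, 1, 0, 1, 0, 1, 0, 1, 1), 5, 2)))
  vals <- t(0.5 + pts %*% t(basis))
  dimnames(vals) <- list(sprintf("cg%02d", 1:5), sprintf("s%d", 1:4))
  bm <- beta_matrix(vals)
  emb <- mds_embed(bm, rownames(vals))
  d_in <- dist(t(vals))
  d_out <- dist(cbind(emb$dim1, emb$dim2))
  expect_equal(as.numeric(d_out), as.numeric(d_in), tolerance = 1e-8)
  # coordinates are centered and ordered by eigenvalue
  expect_equal(mean(emb$dim1), 0, tolerance = 1e-12)
  expect_equal(mean(emb$dim2), 0, tolerance = 1e-12)
  ev <- attr(emb, "eigenvalues")
  expect_gte(ev[1], ev[2])
  # axis sign fixed: first sample nonnegative on both axes
  expect_gte(emb$dim1[1], 0)
  expect_gte(emb$dim2[1], 0)
})

test_that("degenerate MDS inputs collapse gracefully", {
  flat <- beta_matrix(matrix(0.4, 5, 4, dimnames = list(sprintf("cg%d", 1:5),
                                                        sprintf("s%d", 1:4))))
  emb <- mds_embed(flat, rownames(flat))
  expect_true(all(abs(emb$dim1) < 1e-12 & abs(emb$dim2) < 1e-12))

  # single-site panel: centered 1-D ordering, second eigenvalue ~ 0
  one <- beta_matrix(matrix(c(0.1, 0.4, 0.9), 1, 3,
                            dimnames = list("cg1", c("a", "b", "c"))))
  emb1 <- mds_embed(one, "cg1")
  expect_equal(abs(cor(emb1$dim1, c(0.1, 0.4, 0.9))), 1, tolerance = 1e-10)
  expect_equal(mean(emb1$dim1), 0, tolerance = 1e-12)
  expect_lt(abs(attr(emb1, "eigenvalues")[2]), 1e-12)
  expect_true(all(abs(emb1$dim2) < 1e-6))

  expect_error(mds_embed(flat, character(0)), "empty")
})

test_that("module MDS separates serology-defined subgroups as in the cohort design", {
  sim <- medium_cohort()
  mod <- sim$truth$site_id[sim$truth$class == "module"]
  emb <- mds_embed(sim$beta, mod)
  sheet <- sim$sheet
  grp <- ifelse(sheet$group == "disease_A" |
                  (sheet$group == "disease_B" & sheet$serology == "positive"),
                "affected", "unaffected")
  coords <- cbind(emb$dim1, emb$dim2)
  expect_gt(silhouette_mean(coords, grp), 0.3)

  # seronegative disease_B sits nearer the controls than disease A
  centroid <- function(sel) colMeans(coords[sel, , drop = FALSE])
  c_ctrl <- centroid(sheet$group == "control")
  c_A <- centroid(sheet$group == "disease_A")
  c_neg <- centroid(sheet$group == "disease_B" & sheet$serology == "negative")
  expect_lt(sqrt(sum((c_neg - c_ctrl)^2)), sqrt(sum((c_neg - c_A)^2)))
})

test_that("stratified means are plain subgroup means that reaggregate exactly", {
  sim <- medium_cohort()
  mod <- sim$truth$site_id[sim$truth$class == "module"][1:5]
  strat <- stratified_group_means(sim$beta, sim$sheet, mod)
  expect_setequal(unique(strat$subgroup),
                  c("control", "disease_A", "disease_B_seropositive",
                    "disease_B_seronegative"))

  # module effect is driven by the seropositive subgroup
  wide <- tidyr::pivot_wider(strat, id_cols = "site_id",
                             names_from = "subgroup", values_from = "mean_beta")
  expect_true(all(abs(wide$disease_B_seronegative - wide$control) <
                    abs(wide$disease_B_seropositive - wide$control)))

  # recombining the two serology strata weighted by n gives the pooled B mean
  b_samples <- sim$sheet$sample_id[sim$sheet$group == "disease_B"]
  pooled <- rowMeans(unclass(sim$beta)[mod, b_samples])
  ns <- strat[strat$site_id == mod[1], c("subgroup", "n")]
  n_pos <- ns$n[ns$subgroup == "disease_B_seropositive"]
  n_neg <- ns$n[ns$subgroup == "disease_B_seronegative"]
  recomb <- (wide$disease_B_seropositive * n_pos + wide$disease_B_seronegative * n_neg) /
    (n_pos + n_neg)
  expect_equal(unname(pooled), recomb, tolerance = 1e-12)

  # hand-checked arithmetic on a tiny instance
  tiny <- beta_matrix(matrix(c(0.2, 0.4, 0.1, 0.3), 1, 4,
                             dimnames = list("cg1", sprintf("s%d", 1:4))))
  sheet <- tibble::tibble(sample_id = sprintf("s%d", 1:4),
                          group = c("control", "control", "disease_A", "disease_A"),
                          sex = "F", age = 50, serology = "not_applicable")
  expect_warning(st <- stratified_group_means(tiny, sheet, "cg1"), "empty subgroup")
  expect_equal(st$mean_beta[st$subgroup == "control"], 0.3)
  expect_equal(st$mean_beta[st$subgroup == "disease_A"], 0.2)
  expect_true(is.na(st$mean_beta[st$subgroup == "disease_B_seropositive"]))
})

test_that("chi-square enrichment matches the textbook statistic and flags direction", {
  # 2-category toy: background 50/50, observed 10/0
  dmcs <- tibble::tibble(site_id = sprintf("d%02d", 1:10))
  bg <- tibble::tibble(
    site_id = c(dmcs$site_id, sprintf("b%02d", 1:30)),
    chromosome = "chr1", position = 1:40, gene_symbol = "",
    gene_region = rep(c("Body", "TSS200"), each = 20),
    island_relation = "OpenSea"
  )
  # all 10 DMCs in Body; Body and TSS200 each half the background
  res <- regional_enrichment(dmcs, bg, "gene_region")
  expect_equal(attr(res, "statistic"), 10, tolerance = 1e-12)
  expect_equal(attr(res, "p_overall"), 0.001565402, tolerance = 1e-6)

  # textbook oracle as a property over random draws
  withr::with_seed(91, {
    for (i in 1:20) {
      k <- sample(3:6, 1)
      obs <- rpois(k, 40) + 1
      pr <- prop.table(runif(k) + 0.2)
      res <- methcross:::chisq_gof(setNames(obs, paste0("c", 1:k)), pr)
      expect_equal(attr(res, "statistic"),
                   sum((obs - sum(obs) * pr)^2 / (sum(obs) * pr)),
                   tolerance = 1e-10)
    }
  })
})

test_that("enrichment calls are calibrated on null draws and detect construction", {
  sim <- medium_cohort()
  ann <- sim$annotation
  # null draws from the background keep the overall test quiet
  pvals <- withr::with_seed(93, vapply(1:100, function(i) {
    pick <- tibble::tibble(site_id = sample(ann$site_id, 500))
    attr(regional_enrichment(pick, ann, "gene_region"), "p_overall")
  }, numeric(1)))
  expect_gte(mean(pvals > 0.05), 0.94)

  # a gene-body-only set is flagged enriched there and depleted at TSS
  body <- tibble::tibble(site_id = ann$site_id[ann$gene_region == "Body"][1:400])
  res <- regional_enrichment(body, ann, "gene_region")
  expect_identical(res$flag[res$category == "Body"], "enriched")
  expect_true(all(res$flag[res$category %in% c("TSS1500", "TSS200")] == "depleted"))
  expect_equal(sum(res$observed), 400)

  one_cat <- ann; one_cat$gene_region <- "Body"
  expect_error(regional_enrichment(body, one_cat, "gene_region"), "single category")
})

test_that("CpG-peak overlap respects the BED half-open convention", {
  ann <- tibble::tibble(site_id = c("cg1", "cg2"), chromosome = "chr1",
                        position = c(101, 101), gene_symbol = "",
                        gene_region = "Body", island_relation = "Island")
  t1 <- chromatin_track(tibble::tibble(chromosome = "chr1", start = 100, end = 101))
  t2 <- chromatin_track(tibble::tibble(chromosome = "chr1", start = 101, end = 102))
  dm <- tibble::tibble(site_id = c("cg1", "cg2"))
  expect_true(all(chromatin_overlap(dm, ann, t1)$flags$overlap))
  expect_false(any(chromatin_overlap(dm, ann, t2)$flags$overlap))

  # empty track: all flags false; mismatched chromosomes: error
  empty <- chromatin_track(tibble::tibble(chromosome = character(0),
                                          start = numeric(0), end = numeric(0)))
  expect_false(any(chromatin_overlap(dm, ann, empty)$flags$overlap))
  wrong <- chromatin_track(tibble::tibble(chromosome = "1", start = 100, end = 101))
  expect_error(chromatin_overlap(dm, ann, wrong), "chromosome names")
})

test_that("overlap flags are invariant to interval order and abutting splits", {
  withr::with_seed(95, {
    ann <- tibble::tibble(site_id = sprintf("cg%04d", 1:1000),
                          chromosome = paste0("chr", sample.int(3, 1000, TRUE)),
                          position = sample.int(10000, 1000, TRUE),
                          gene_symbol = "", gene_region = "Body",
                          island_relation = "OpenSea")
    start <- sort(sample.int(9000, 50))
    iv <- tibble::tibble(chromosome = paste0("chr", sample.int(3, 50, TRUE)),
                         start = start, end = start + sample.int(400, 50))
  })
  dm <- tibble::tibble(site_id = ann$site_id)
  base <- chromatin_overlap(dm, ann, chromatin_track(iv))$flags$overlap
  shuf <- chromatin_overlap(dm, ann, chromatin_track(iv[rev(seq_len(50)), ]))$flags$overlap
  expect_identical(base, shuf)

  mid <- floor((iv$start + iv$end) / 2)
  split <- tibble::tibble(
    chromosome = rep(iv$chromosome, 2),
    start = c(iv$start, mid), end = c(mid, iv$end)
  )
  split <- split[split$start < split$end, ]
  expect_identical(base,
                   chromatin_overlap(dm, ann, chromatin_track(split))$flags$overlap)

  # overlap fraction matches the exact covered-position fraction (positions
  # uniform on 1..10000 per chromosome), brute-forced position by position
  cov_frac <- mean(vapply(paste0("chr", 1:3), function(chr) {
    covered <- logical(10000)
    for (r in which(iv$chromosome == chr)) {
      lo <- iv$start[r] + 1; hi <- min(iv$end[r], 10000)
      if (lo <= hi) covered[lo:hi] <- TRUE
    }
    mean(covered)
  }, numeric(1)))
  expect_equal(mean(base), cov_frac,
               tolerance = 3 * sqrt(cov_frac * (1 - cov_frac) / 1000) / cov_frac)
})
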