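#' Simulation design for a three-group methylation cohort
#'
#' Describes a synthetic cohort of controls plus two diseases (an SLE-like
#' `disease_A` and a pSS-like `disease_B`) with planted differential
#' methylation. Defaults mirror the scale of a two-disease blood EWAS divided
#' by ten (400/347/100 samples -> 40/35/10; 385,962 post-QC autosomal sites
#' -> 20,000) so a full run stays desk-scale. Effect structure emulates the
#' field's findings: a majority-hypomethylated shared component, intermediate
#' effect sizes in `disease_B`, an interferon-like gene module driven by the
#' serology-positive `disease_B` subgroup (and all of `disease_A`), cell-type
#' composition confounding, and age/sex covariate effects.
#'
#' @param n_control,n_A,n_B Samples per group.
#' @param n_sites CpG sites in the simulated universe.
#' @param n_shared,n_unique_A,n_unique_B Planted differentially methylated
#'   sites of each cross-disease class.
#' @param n_module_sites Sites in the interferon-like module (shifted in all
#'   `disease_A` samples and in serology-positive `disease_B` samples only).
#' @param frac_hypo Fraction of planted shared/unique effects with negative
#'   (hypomethylated-in-cases) direction; module sites are always hypo.
#' @param delta_A,delta_B Target |delta-beta| for planted effects in each
#'   disease; `delta_B <= delta_A` (disease B intermediate).
#' @param frac_seropositive Fraction of `disease_B` that is serology
#'   positive (autoantibody-positive analogue).
#' @param precision Beta-distribution concentration of measurement noise;
#'   per-site SD is roughly `sqrt(m * (1 - m) / (precision + 1))`.
#' @param age_effect,sex_effect Additive covariate effects on the latent
#'   logit scale (per year of age; male vs female).
#' @param confound_strength Group-wise shift of the disease groups' mean cell
#'   proportions towards granulocytes (fraction of the simplex moved).
#' @param cell_concentration Dirichlet concentration of per-sample cell
#'   proportions around the group base composition.
#' @param seed Integer seed; the whole cohort is a deterministic function of
#'   the design.
#'
#' @return A `simulation_design` list.
#' @export
simulation_design <- function(n_control = 40, n_A = 35, n_B = 10,
                              n_sites = 20000,
                              n_shared = 300, n_unique_A = 100, n_unique_B = 50,
                              n_module_sites = 30,
                              frac_hypo = 0.72,
                              delta_A = 0.2, delta_B = 0.14,
                              frac_seropositive = 0.75,
                              precision = 100,
                              age_effect = 0.002, sex_effect = 0.05,
                              confound_strength = 0.1,
                              cell_concentration = 150,
                              seed = 1L) {
  design <- list(
    n_control = n_control, n_A = n_A, n_B = n_B, n_sites = n_sites,
    n_shared = n_shared, n_unique_A = n_unique_A, n_unique_B = n_unique_B,
    n_module_sites = n_module_sites, frac_hypo = frac_hypo,
    delta_A = delta_A, delta_B = delta_B,
    frac_seropositive = frac_seropositive, precision = precision,
    age_effect = age_effect, sex_effect = sex_effect,
    confound_strength = confound_strength,
    cell_concentration = cell_concentration, seed = as.integer(seed)
  )
  validate_simulation_design(design)
  structure(design, class = "simulation_design")
}

validate_simulation_design <- function(d) {
  n_planted <- d$n_shared + d$n_unique_A + d$n_unique_B + d$n_module_sites
  if (n_planted > d$n_sites) abort("planted site counts exceed n_sites")
  if (d$frac_hypo <= 0 || d$frac_hypo > 1) abort("frac_hypo must be in (0, 1]")
  if (d$delta_B > d$delta_A) abort("delta_B must not exceed delta_A (disease B is intermediate)")
  if (d$frac_seropositive < 0 || d$frac_seropositive > 1) abort("frac_seropositive must be in [0, 1]")
  if (d$precision <= 0) abort("precision must be > 0")
  if (d$confound_strength < 0 || d$confound_strength > 1) abort("confound_strength must be in [0, 1]")
  if (min(d$n_control, d$n_A, d$n_B) < 2) abort("each group needs >= 2 samples")
  invisible(d)
}

default_cell_types <- function() {
  c("CD4T", "CD8T", "NK", "Bcell", "Monocyte", "Granulocyte")
}

default_cell_base <- function(cell_types) {
  if (identical(cell_types, default_cell_types())) {
    c(CD4T = 0.15, CD8T = 0.10, NK = 0.05, Bcell = 0.08,
      Monocyte = 0.07, Granulocyte = 0.55)
  } else {
    setNames(rep(1 / length(cell_types), length(cell_types)), cell_types)
  }
}

#' Simulate reference methylomes of sorted blood cell types
#'
#' Builds per-cell-type mean beta profiles of the kind used for
#' reference-based deconvolution. Each cell type receives
#' `n_discriminating_per_type` marker sites at which its methylation differs
#' from every other type by at least 0.5 (half hyper-, half hypomethylated
#' relative to the shared level); all remaining sites share a common
#' baseline drawn from a bimodal methylome-like distribution, with small
#' cell-type-specific deviations (at most `profile_scatter` in beta) so that
#' composition differences leave a genome-wide footprint as they do in real
#' whole-blood data.
#'
#' @param n_celltypes Number of cell types (>= 2).
#' @param n_sites Number of CpG sites.
#' @param n_discriminating_per_type Marker sites per cell type.
#' @param seed Integer seed.
#' @param cell_types Optional labels; defaults to the six canonical blood
#'   types when `n_celltypes == 6`.
#' @param profile_scatter Half-width of the per-type uniform deviation at
#'   non-marker sites (beta scale); must be < 0.25 so only planted markers
#'   can reach a between-type gap of 0.5.
#' @return A `reference_profiles` matrix (sites x cell types) with a
#'   `discriminating` attribute listing the planted marker sites.
#' @export
simulate_reference_profiles <- function(n_celltypes, n_sites,
                                        n_discriminating_per_type, seed = 1L,
                                        cell_types = NULL,
                                        profile_scatter = 0.1) {
  if (n_celltypes < 2) abort("deconvolution needs >= 2 cell types")
  if (n_celltypes * n_discriminating_per_type > n_sites) {
    abort("requested discriminating sites exceed n_sites")
  }
  if (profile_scatter < 0 || profile_scatter >= 0.25) {
    abort("profile_scatter must be in [0, 0.25)")
  }
  if (is.null(cell_types)) {
    cell_types <- if (n_celltypes == 6) default_cell_types() else
      paste0("cell", seq_len(n_celltypes))
  }
  withr::with_seed(as.integer(seed), {
    baseline <- draw_bimodal_baseline(n_sites)
    sid <- sprintf("cg%07d", seq_len(n_sites))
    values <- matrix(rep(baseline, n_celltypes), ncol = n_celltypes,
                     dimnames = list(sid, cell_types))
    # small type-specific deviations at non-marker sites (gap < 2 * 0.25 < 0.5)
    dev <- matrix(runif(n_sites * n_celltypes, -profile_scatter, profile_scatter),
                  ncol = n_celltypes)
    values <- pmin(pmax(values + dev, 0.02), 0.98)
    n_disc <- n_discriminating_per_type
    disc_idx <- seq_len(n_celltypes * n_disc)
    disc <- tibble(
      site_id = sid[disc_idx],
      cell_type = rep(cell_types, each = n_disc),
      direction = rep_len(c("hyper", "hypo"), n_celltypes * n_disc)
    )
    for (k in seq_along(disc_idx)) {
      i <- disc_idx[k]
      hyper <- disc$direction[k] == "hyper"
      shared <- runif(1, 0.15, 0.25)
      if (!hyper) shared <- 1 - shared
      marker <- shared + (if (hyper) 1 else -1) * runif(1, 0.55, 0.7)
      values[i, ] <- shared
      values[i, disc$cell_type[k]] <- min(max(marker, 0.02), 0.98)
    }
    structure(values, discriminating = disc,
              class = c("reference_profiles", class(matrix())))
  })
}

# methylome-like bimodal marginal: mostly low or high, some intermediate
draw_bimodal_baseline <- function(n) {
  comp <- sample.int(3, n, replace = TRUE, prob = c(0.4, 0.4, 0.2))
  b <- numeric(n)
  b[comp == 1] <- rbeta(sum(comp == 1), 2.5, 10)   # unmethylated tail
  b[comp == 2] <- rbeta(sum(comp == 2), 10, 2.5)   # methylated tail
  b[comp == 3] <- rbeta(sum(comp == 3), 6, 6)      # intermediate
  pmin(pmax(b, 0.02), 0.98)
}

#' @export
print.reference_profiles <- function(x, ...) {
  cat(sprintf("<reference_profiles> %d sites x %d cell types (%s)\n",
              nrow(x), ncol(x), paste(colnames(x), collapse = ", ")))
  invisible(x)
}

#' Simulate a three-group cohort with planted ground truth
#'
#' Generates the full set of study inputs: a beta matrix, a sample sheet, a
#' CpG annotation table and the planted ground truth. Per sample, cell-type
#' proportions are drawn from a Dirichlet around a group base composition
#' (shifted towards granulocytes in the disease groups by
#' `confound_strength`); per site, the latent methylation level is the cell
#' mixture of the reference profiles with planted group effects and linear
#' age/sex effects added on the logit scale and back-transformed; the
#' observed beta is a draw from a beta distribution with that mean and the
#' design's `precision`. Planted effects are placed only at non-marker sites
#' so the deconvolution signature stays clean. Shared sites shift in both
#' diseases with the same sign (`delta_A` in A, `delta_B` in B); unique
#' sites shift in one disease only; module sites shift (always downward) in
#' all of `disease_A` and in serology-positive `disease_B` samples only.
#'
#' @param design A [simulation_design()].
#' @param reference Optional [simulate_reference_profiles()] output with
#'   `n_sites` rows; by default a six-type reference with 60 markers per
#'   type is generated from the design seed.
#' @return A list with elements `beta` ([beta_matrix()]), `sheet`
#'   (sample-sheet tibble), `annotation` (CpG annotation tibble), `truth`
#'   (ground-truth tibble: `site_id`, `class`, `direction`, realized
#'   `delta_A`/`delta_B` as latent group-mean differences vs control), and
#'   `reference`.
#' @export
simulate_cohort <- function(design, reference = NULL) {
  validate_simulation_design(design)
  if (is.null(reference)) {
    reference <- simulate_reference_profiles(
      n_celltypes = 6, n_sites = design$n_sites,
      n_discriminating_per_type = 60, seed = design$seed + 104729L
    )
  }
  if (nrow(reference) != design$n_sites) {
    abort("reference profiles must cover exactly n_sites rows")
  }
  withr::with_seed(design$seed, simulate_cohort_impl(design, reference))
}

simulate_cohort_impl <- function(design, reference) {
  sid <- rownames(reference)
  cell_types <- colnames(reference)
  n <- design$n_control + design$n_A + design$n_B
  group <- rep(c("control", "disease_A", "disease_B"),
               c(design$n_control, design$n_A, design$n_B))
  sample_id <- sprintf("S%03d", seq_len(n))
  sex <- ifelse(runif(n) < 0.88, "F", "M")
  age <- pmin(pmax(rnorm(n, 47, 15), 20), 80)
  serology <- rep("not_applicable", n)
  b_idx <- which(group == "disease_B")
  n_pos <- round(design$frac_seropositive * design$n_B)
  serology[b_idx] <- c(rep("positive", n_pos), rep("negative", design$n_B - n_pos))

  # per-sample cell proportions (Dirichlet; disease groups shifted)
  base <- default_cell_base(cell_types)
  shift <- rep(0, length(base)); shift[length(base)] <- 1
  base_case <- base * (1 - design$confound_strength) + shift * design$confound_strength
  w <- t(vapply(seq_len(n), function(i) {
    b <- if (group[i] == "control") base else base_case
    rdirichlet1(b * design$cell_concentration)
  }, numeric(length(base))))
  colnames(w) <- cell_types

  # site-level baseline under the control-base mixture; planted sites are
  # drawn only where the target shift has headroom on the beta scale
  m_ref <- as.vector(unclass(reference) %*% base)
  m_ref <- pmin(pmax(m_ref, 1e-4), 1 - 1e-4)
  names(m_ref) <- sid

  disc_sites <- attr(reference, "discriminating")$site_id
  free <- setdiff(sid, disc_sites)
  counts <- c(shared = design$n_shared, unique_A = design$n_unique_A,
              unique_B = design$n_unique_B, module = design$n_module_sites)
  if (sum(counts) > length(free)) abort("not enough non-marker sites for the planted classes")

  planted_class <- rep(names(counts), counts)
  planted_dir <- ifelse(runif(length(planted_class)) < design$frac_hypo, "hypo", "hyper")
  planted_dir[planted_class == "module"] <- "hypo"  # IFN-like module: coordinate hypomethylation
  pool_hypo <- sample(free[m_ref[free] >= design$delta_A + 0.03])
  pool_hyper <- sample(free[m_ref[free] <= 0.97 - design$delta_A])
  pool_hyper <- setdiff(pool_hyper, pool_hypo[seq_len(min(sum(planted_dir == "hypo"),
                                                          length(pool_hypo)))])
  if (sum(planted_dir == "hypo") > length(pool_hypo) ||
      sum(planted_dir == "hyper") > length(pool_hyper)) {
    abort("not enough sites with beta-scale headroom for the planted effect sizes")
  }
  picked <- character(length(planted_class))
  picked[planted_dir == "hypo"] <- pool_hypo[seq_len(sum(planted_dir == "hypo"))]
  picked[planted_dir == "hyper"] <- pool_hyper[seq_len(sum(planted_dir == "hyper"))]

  class_of <- setNames(rep("null", length(sid)), sid)
  class_of[picked] <- planted_class
  direction <- setNames(rep(NA_character_, length(sid)), sid)
  direction[picked] <- planted_dir
  planted <- class_of != "null"

  # latent means: cell mixture, then effects on the logit scale
  mu0 <- unclass(reference) %*% t(w)            # sites x samples
  mu0 <- pmin(pmax(mu0, 1e-4), 1 - 1e-4)
  covariate_shift <- design$age_effect * (age - 47) + design$sex_effect * (sex == "M")
  eta <- qlogis(mu0) +
    matrix(covariate_shift, nrow = length(sid), ncol = n, byrow = TRUE)

  # per-site logit shift sized so the beta-scale shift is ~delta at the
  # control-base mixture level
  shift_for <- function(idx, delta) {
    sgn <- ifelse(direction[idx] == "hypo", -1, 1)
    target <- pmin(pmax(m_ref[idx] + sgn * delta, 0.02), 0.98)
    qlogis(target) - qlogis(m_ref[idx])
  }
  site_index <- setNames(seq_along(sid), sid)
  in_A <- group == "disease_A"
  in_B <- group == "disease_B"
  in_Bpos <- in_B & serology == "positive"
  add_effect <- function(eta, sites, samples, delta) {
    if (length(sites) == 0 || !any(samples)) return(eta)
    idx <- site_index[sites]
    eta[idx, samples] <- eta[idx, samples] + shift_for(idx, delta)
    eta
  }
  shared_sites <- names(class_of)[class_of == "shared"]
  uA_sites <- names(class_of)[class_of == "unique_A"]
  uB_sites <- names(class_of)[class_of == "unique_B"]
  mod_sites <- names(class_of)[class_of == "module"]
  eta <- add_effect(eta, shared_sites, in_A, design$delta_A)
  eta <- add_effect(eta, shared_sites, in_B, design$delta_B)
  eta <- add_effect(eta, uA_sites, in_A, design$delta_A)
  eta <- add_effect(eta, uB_sites, in_B, design$delta_B)
  eta <- add_effect(eta, mod_sites, in_A, design$delta_A)
  eta <- add_effect(eta, mod_sites, in_Bpos, design$delta_B)

  mu <- plogis(eta)
  obs <- matrix(
    rbeta(length(mu), shape1 = as.vector(mu) * design$precision,
          shape2 = (1 - as.vector(mu)) * design$precision),
    nrow = nrow(mu), dimnames = list(sid, sample_id)
  )
  obs <- pmin(pmax(obs, 1e-6), 1 - 1e-6)

  ctrl <- group == "control"
  truth_sites <- names(class_of)[planted]
  ti <- site_index[truth_sites]
  truth <- tibble(
    site_id = truth_sites,
    class = unname(class_of[truth_sites]),
    direction = unname(direction[truth_sites]),
    delta_A = rowMeans(mu[ti, in_A, drop = FALSE]) - rowMeans(mu[ti, ctrl, drop = FALSE]),
    delta_B = rowMeans(mu[ti, in_B, drop = FALSE]) - rowMeans(mu[ti, ctrl, drop = FALSE])
  )
  null_truth <- tibble(
    site_id = names(class_of)[!planted], class = "null",
    direction = NA_character_, delta_A = 0, delta_B = 0
  )
  truth <- bind_rows(truth, null_truth)
  truth <- truth[match(sid, truth$site_id), ]

  sheet <- tibble(sample_id = sample_id, group = group, sex = sex,
                  age = round(age, 1), serology = serology)
  cellprop <- as_tibble(w)
  names(cellprop) <- paste0("true_", names(cellprop))
  sheet <- dplyr::bind_cols(sheet, cellprop)

  list(
    beta = beta_matrix(obs),
    sheet = sheet,
    annotation = simulate_annotation(sid, class_of),
    truth = truth,
    reference = reference
  )
}

# uniform-ish annotation across 22 autosomes with module sites given gene
# symbols from a fixed interferon-regulated panel
simulate_annotation <- function(sid, class_of) {
  n <- length(sid)
  chrom <- paste0("chr", sample.int(22, n, replace = TRUE))
  pos <- sample.int(2e8, n, replace = TRUE)
  genes <- ifelse(runif(n) < 0.7, sprintf("GENE%04d", sample.int(3000, n, replace = TRUE)), "")
  ifn_panel <- c("IFI44L", "IFIT1", "IFITM1", "IFITM3", "IRF7",
                 "MX1", "OAS1", "PARP9", "PLSCR1", "RSAD2")
  mod <- which(class_of == "module")
  if (length(mod) > 0) genes[mod] <- rep_len(ifn_panel, length(mod))
  tibble(
    site_id = sid, chromosome = chrom, position = pos, gene_symbol = genes,
    gene_region = sample(gene_region_levels(), n, replace = TRUE,
                         prob = c(0.12, 0.08, 0.06, 0.05, 0.34, 0.04, 0.31)),
    island_relation = sample(island_relation_levels(), n, replace = TRUE,
                             prob = c(0.31, 0.23, 0.10, 0.36))
  )
}

rdirichlet1 <- function(alpha) {
  g <- rgamma(length(alpha), shape = alpha, rate = 1)
  g / sum(g)
}

#' Confusion counts of a called site set against planted truth
#'
#' @param called Character vector of called site ids, or a `dmc_set` /
#'   tibble with a `site_id` column.
#' @param truth Ground-truth tibble from [simulate_cohort()].
#' @param positive_classes Truth classes counted as positives (default every
#'   planted class).
#' @return One-row tibble with `tp`, `fp`, `fn`, `sensitivity`
#'   (`tp / (tp + fn)`) and `fdp` (`fp / max(1, tp + fp)`); the per-truth-class
#'   breakdown of called sites is attached as attribute `by_class`.
#' @export
truth_confusion <- function(called, truth,
                            positive_classes = c("shared", "unique_A",
                                                 "unique_B", "module")) {
  if (is.data.frame(called)) called <- called$site_id
  called <- unique(as.character(called))
  unknown <- setdiff(called, truth$site_id)
  if (length(unknown) > 0) {
    abort(paste0("called site(s) outside the truth universe: ",
                 paste(head(unknown, 5), collapse = ", ")))
  }
  pos <- truth$site_id[truth$class %in% positive_classes]
  tp <- length(intersect(called, pos))
  fp <- length(setdiff(called, pos))
  fn <- length(setdiff(pos, called))
  by_class <- truth |>
    mutate(called = .data$site_id %in% called) |>
    group_by(.data$class) |>
    summarise(n_truth = n(), n_called = sum(.data$called), .groups = "drop")
  structure(
    tibble(tp = tp, fp = fp, fn = fn,
           sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
           fdp = fp / max(1L, tp + fp)),
    by_class = by_class
  )
}
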