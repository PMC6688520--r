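#' Classical multidimensional scaling of samples over a signature panel
#'
#' Embeds samples in two dimensions by classical (Torgerson) scaling of
#' pairwise Euclidean distances computed over a CpG panel — e.g. DMCs at
#' interferon-regulated genes, which visually separates serology-defined
#' subgroups. Axis signs are fixed by forcing the first sample's coordinate
#' to be nonnegative on each axis, so the embedding is reproducible.
#'
#' @param beta A [beta_matrix()].
#' @param panel Character vector of site ids (subset of the matrix rows).
#' @return An `mds_embedding` tibble: `sample_id`, `dim1`, `dim2`;
#'   attributes `eigenvalues` (all scaling eigenvalues, decreasing) and
#'   `panel`.
#' @export
mds_embed <- function(beta, panel) {
  if (length(panel) == 0) abort("panel is empty")
  missing_sites <- setdiff(panel, rownames(beta))
  if (length(missing_sites) > 0) {
    abort(paste0("panel site(s) absent from beta matrix: ",
                 paste(head(missing_sites, 5), collapse = ", ")))
  }
  if (ncol(beta) < 3) abort("MDS needs >= 3 samples")
  M <- t(unclass(beta)[panel, , drop = FALSE])   # samples x sites
  d <- dist(M)
  k <- min(2, nrow(M) - 1)
  sc <- suppressWarnings(cmdscale(d, k = k, eig = TRUE))
  pts <- sc$points
  if (is.null(pts) || ncol(pts) < 2) {
    pad <- matrix(0, nrow(M), 2 - ifelse(is.null(pts), 0, ncol(pts)))
    pts <- cbind(pts, pad)
  }
  pts <- pts[, 1:2, drop = FALSE]
  for (j in 1:2) if (pts[1, j] < 0) pts[, j] <- -pts[, j]
  out <- tibble(sample_id = rownames(M), dim1 = pts[, 1], dim2 = pts[, 2])
  structure(out, eigenvalues = sc$eig, panel = panel,
            class = c("mds_embedding", class(out)))
}

#' Mean methylation per serology-stratified subgroup
#'
#' Splits the cohort into control, disease_A, serology-positive disease_B
#' and serology-negative disease_B, and reports the mean beta per subgroup
#' at each panel site — the stratification that reveals whether a module
#' effect is driven by the seropositive subgroup.
#'
#' @inheritParams mds_embed
#' @param sheet Sample sheet.
#' @return Tibble: `site_id`, `subgroup`, `n`, `mean_beta` (NA with a
#'   warning for an empty subgroup).
#' @export
stratified_group_means <- function(beta, sheet, panel) {
  if (length(panel) == 0) abort("panel is empty")
  sheet <- validate_sample_sheet(sheet)
  subgroup <- dplyr::case_when(
    sheet$group == "control" ~ "control",
    sheet$group == "disease_A" ~ "disease_A",
    sheet$serology == "positive" ~ "disease_B_seropositive",
    TRUE ~ "disease_B_seronegative"
  )
  levels <- c("control", "disease_A", "disease_B_seropositive", "disease_B_seronegative")
  empty <- setdiff(levels, unique(subgroup))
  if (length(empty) > 0) {
    warn(paste0("empty subgroup(s): ", paste(empty, collapse = ", "), "; means reported as NA"))
  }
  B <- unclass(beta)[panel, sheet$sample_id, drop = FALSE]
  purrr::map_dfr(levels, function(g) {
    idx <- which(subgroup == g)
    tibble(site_id = panel, subgroup = g, n = length(idx),
           mean_beta = if (length(idx) > 0)
             unname(rowMeans(B[, idx, drop = FALSE])) else NA_real_)
  })
}

# chi-square goodness of fit of observed category counts against background
# proportions, with standardized-residual post-hoc flags and an exact
# (binomial) fallback when expected counts drop below 5
chisq_gof <- function(observed, bg_props, alpha = 0.05) {
  stopifnot(length(observed) == length(bg_props))
  if (length(observed) < 2) abort("enrichment needs >= 2 categories in the background")
  if (any(bg_props <= 0)) abort("background categories must all have nonzero probability")
  n <- sum(observed)
  expected <- n * bg_props
  small <- any(expected < 5)
  if (small) {
    warn("expected count < 5 in some category; using Monte-Carlo/exact p-values")
    ct <- suppressWarnings(chisq.test(observed, p = bg_props,
                                      simulate.p.value = TRUE, B = 20000))
  } else {
    ct <- chisq.test(observed, p = bg_props)
  }
  stdres <- (observed - expected) / sqrt(expected * (1 - bg_props))
  p_cat <- if (small) {
    vapply(seq_along(observed), function(i) {
      binom.test(observed[i], n, bg_props[i])$p.value
    }, numeric(1))
  } else {
    2 * stats::pnorm(-abs(stdres))
  }
  divisor <- length(observed)
  flag <- dplyr::case_when(
    p_cat < alpha / divisor & observed > expected ~ "enriched",
    p_cat < alpha / divisor & observed < expected ~ "depleted",
    TRUE ~ "ns"
  )
  out <- tibble(
    category = names(observed) %||% as.character(seq_along(observed)),
    observed = as.integer(observed), expected = expected,
    stdres = stdres, p_category = p_cat, flag = flag
  )
  structure(out,
            statistic = unname(ct$statistic), p_overall = ct$p.value,
            df = length(observed) - 1, bonferroni_divisor = divisor,
            alpha = alpha, exact_fallback = small,
            class = c("enrichment_result", class(out)))
}

#' Functional-region enrichment of a DMC set
#'
#' Compares the distribution of a DMC set over gene-region or CpG-island
#' relation categories against the full tested probe background with a
#' chi-square goodness-of-fit test. Per-category enrichment/depletion flags
#' come from standardized residuals at a Bonferroni-corrected level whose
#' divisor is the number of categories actually tested in the run (the
#' divisor is reported, never hard-coded). Expected counts below 5 trigger a
#' warning and an exact/Monte-Carlo fallback.
#'
#' @param dmcs A `dmc_set` (or tibble with `site_id`).
#' @param background CpG annotation of the full tested site universe; every
#'   DMC site must be annotated.
#' @param feature `"gene_region"` or `"island_relation"`.
#' @param alpha Family-wise level for the per-category flags.
#' @return An `enrichment_result` tibble (category, observed, expected,
#'   stdres, p_category, flag) with attributes `statistic`, `p_overall`,
#'   `df`, `bonferroni_divisor`.
#' @export
regional_enrichment <- function(dmcs, background,
                                feature = c("gene_region", "island_relation"),
                                alpha = 0.05) {
  feature <- match.arg(feature)
  df <- as_tibble(dmcs)
  if (nrow(df) < 1) abort("DMC set is empty")
  background <- as_tibble(background)
  missing_sites <- setdiff(df$site_id, background$site_id)
  if (length(missing_sites) > 0) {
    abort(paste0("DMC site(s) missing from the background annotation: ",
                 paste(head(missing_sites, 5), collapse = ", ")))
  }
  cats <- sort(unique(background[[feature]]))
  if (length(cats) < 2) abort("background has a single category; enrichment undefined")
  bg_counts <- table(factor(background[[feature]], levels = cats))
  fg <- background[[feature]][match(df$site_id, background$site_id)]
  observed <- table(factor(fg, levels = cats))
  chisq_gof(setNames(as.integer(observed), cats),
            as.numeric(bg_counts) / sum(bg_counts), alpha = alpha)
}

#' Overlap of DMCs with chromatin-mark peaks
#'
#' Flags each DMC whose genomic position falls inside a peak of the given
#' chromatin track, and tests overlap enrichment against the full annotated
#' background with the same chi-square machinery as
#' [regional_enrichment()]. A CpG at 1-based position `p` overlaps a
#' 0-based half-open interval `[s, e)` iff `s <= p - 1 < e`; annotation and
#' track must be on the same genome assembly (the caller's responsibility).
#'
#' @param dmcs A `dmc_set` (or tibble with `site_id`).
#' @param annotation CpG annotation covering the DMC sites and the
#'   background universe.
#' @param track A `chromatin_track`.
#' @param alpha Family-wise level for the enrichment flags.
#' @return List with `flags` (tibble: `site_id`, `chromosome`, `position`,
#'   `overlap`) and `enrichment` (an `enrichment_result` over
#'   overlap/no-overlap counts).
#' @export
chromatin_overlap <- function(dmcs, annotation, track, alpha = 0.05) {
  df <- as_tibble(dmcs)
  annotation <- as_tibble(annotation)
  missing_sites <- setdiff(df$site_id, annotation$site_id)
  if (length(missing_sites) > 0) {
    abort(paste0("DMC site(s) missing from annotation: ",
                 paste(head(missing_sites, 5), collapse = ", ")))
  }
  track_tbl <- as_tibble(track)
  unmatched <- setdiff(unique(track_tbl$chromosome), unique(annotation$chromosome))
  if (length(unmatched) == length(unique(track_tbl$chromosome)) && nrow(track_tbl) > 0) {
    abort(paste0("chromosome names of track and annotation do not match; unmatched: ",
                 paste(head(unmatched, 10), collapse = ", ")))
  }
  bg_flags <- overlap_flags(annotation, track_tbl)
  fg_idx <- match(df$site_id, annotation$site_id)
  flags <- tibble(
    site_id = df$site_id,
    chromosome = annotation$chromosome[fg_idx],
    position = annotation$position[fg_idx],
    overlap = bg_flags[fg_idx]
  )
  observed <- c(overlap = sum(flags$overlap), no_overlap = sum(!flags$overlap))
  bg_prop <- mean(bg_flags)
  enr <- if (bg_prop > 0 && bg_prop < 1) {
    chisq_gof(observed, c(bg_prop, 1 - bg_prop), alpha = alpha)
  } else {
    NULL
  }
  list(flags = flags, enrichment = enr)
}

# per-site logical: does the (1-based) CpG position fall inside any 0-based
# half-open track interval on the same chromosome?
overlap_flags <- function(annotation, track_tbl) {
  flags <- logical(nrow(annotation))
  if (nrow(track_tbl) == 0) return(flags)
  for (chr in intersect(unique(annotation$chromosome), unique(track_tbl$chromosome))) {
    ai <- which(annotation$chromosome == chr)
    ti <- track_tbl[track_tbl$chromosome == chr, , drop = FALSE]
    # [s, e) 0-based  ==  [s + 1, e] 1-based closed
    subject <- IRanges::IRanges(start = ti$start + 1, end = ti$end)
    query <- IRanges::IRanges(start = annotation$position[ai], width = 1)
    hits <- IRanges::overlapsAny(query, subject)
    flags[ai] <- hits
  }
  flags
}
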