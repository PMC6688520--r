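#' Classify one disease's DMCs as shared with the other disease
#'
#' A DMC from one case-control EWAS is *shared* when, in the other disease's
#' case-control EWAS, it reaches `shared_p_cutoff` with the same direction of
#' effect. The cutoff is derived once — Bonferroni at 0.05 over the DMC count
#' of a designated reference disease — and the same cutoff is applied in both
#' directions. Sites whose `delta_beta` is exactly zero in either EWAS cannot
#' be concordant and are excluded.
#'
#' @param dmcs_own `dmc_set` from the disease's own case-control EWAS.
#' @param ewas_other `ewas_result` of the other disease vs control; must
#'   cover every site of `dmcs_own`.
#' @param shared_p_cutoff Sharing p-value cutoff (see
#'   [bonferroni_threshold()]).
#' @return Tibble of shared sites: `site_id`, `p_own`, `delta_own`,
#'   `p_other`, `delta_other`.
#' @export
classify_shared <- function(dmcs_own, ewas_other, shared_p_cutoff) {
  paired <- pair_with_other(dmcs_own, ewas_other)
  paired |>
    filter(.data$p_other < shared_p_cutoff,
           sign(.data$delta_own) == sign(.data$delta_other),
           .data$delta_own != 0)
}

#' Classify one disease's DMCs as unique to it
#'
#' A DMC is *unique* to its disease when the other disease's case-control
#' EWAS shows no signal at that site: unadjusted `p > 0.05` (strict). Sites
#' between the sharing cutoff and 0.05 fall in neither set; see
#' [classify_cross_disease()] for the full partition.
#'
#' @inheritParams classify_shared
#' @return Tibble of unique sites with both EWASs' `p` and `delta_beta`.
#' @export
classify_unique <- function(dmcs_own, ewas_other) {
  pair_with_other(dmcs_own, ewas_other) |>
    filter(.data$p_other > 0.05)
}

pair_with_other <- function(dmcs_own, ewas_other) {
  own <- as_tibble(dmcs_own)
  other <- as_tibble(ewas_other)
  missing_sites <- setdiff(own$site_id, other$site_id)
  if (length(missing_sites) > 0) {
    abort(paste0("site universes differ: DMC site(s) absent from the other EWAS: ",
                 paste(head(missing_sites, 5), collapse = ", ")))
  }
  own |>
    select("site_id", p_own = "p", delta_own = "delta_beta") |>
    left_join(select(other, "site_id", p_other = "p", delta_other = "delta_beta"),
              by = "site_id")
}

#' Merge the two directed shared-DMC lists into a combined set
#'
#' The union of the shared sites found from disease A's DMCs and from
#' disease B's DMCs, keyed by site id with duplicates removed; provenance
#' records which direction(s) contributed each site.
#'
#' @param from_A,from_B Tibbles from [classify_shared()] (need a `site_id`
#'   column; other columns are carried from whichever list supplies the
#'   site, preferring A's row for sites found in both).
#' @return A `shared_dmc_set` tibble with a `provenance` column in
#'   `{from_A_dmcs, from_B_dmcs, both}`.
#' @export
combine_shared_sets <- function(from_A, from_B) {
  a <- as_tibble(from_A); b <- as_tibble(from_B)
  in_both <- intersect(a$site_id, b$site_id)
  out <- bind_rows(a, b[!b$site_id %in% a$site_id, , drop = FALSE])
  out$provenance <- ifelse(out$site_id %in% in_both, "both",
                           ifelse(out$site_id %in% a$site_id, "from_A_dmcs", "from_B_dmcs"))
  structure(distinct(out, .data$site_id, .keep_all = TRUE),
            class = c("shared_dmc_set", class(out)))
}

#' Summarise hypo/hyper direction counts of a DMC set
#'
#' @param set A `dmc_set`, `shared_dmc_set`, or any tibble with either a
#'   `direction` column or a signed effect column (`delta_beta` or
#'   `delta_own`).
#' @return One-row tibble: `n`, `n_hypo`, `n_hyper`, `pct_hypo`, `pct_hyper`
#'   (nearest-integer percentages; `NA` for an empty set).
#' @examples
#' summarize_directions(tibble::tibble(delta_beta = c(-0.1, -0.2, 0.3)))
#' @export
summarize_directions <- function(set) {
  df <- as_tibble(set)
  if (nrow(df) == 0) {
    return(tibble(n = 0L, n_hypo = 0L, n_hyper = 0L,
                  pct_hypo = NA_real_, pct_hyper = NA_real_))
  }
  dir <- if ("direction" %in% names(df)) {
    df$direction
  } else {
    eff <- if ("delta_beta" %in% names(df)) df[["delta_beta"]] else df[["delta_own"]]
    if (is.null(eff)) abort("no direction or signed effect column found")
    ifelse(eff < 0, "hypo", "hyper")
  }
  n_hypo <- sum(dir == "hypo"); n_hyper <- sum(dir == "hyper")
  tibble(n = nrow(df), n_hypo = n_hypo, n_hyper = n_hyper,
         pct_hypo = round(100 * n_hypo / nrow(df)),
         pct_hyper = round(100 * n_hyper / nrow(df)))
}

#' Full cross-disease partition of two case-control EWASs
#'
#' Applies the whole classification scheme: calls DMCs in each disease,
#' derives the sharing cutoff from the reference disease's DMC count,
#' classifies shared and unique DMCs in both directions, merges the combined
#' shared set, and labels the remainder. Each disease's DMCs partition into
#' `shared`, `unique`, `indeterminate` (other-disease p between the sharing
#' cutoff and 0.05 — deliberately kept, not forced into either set) and
#' `discordant` (other-disease p below the sharing cutoff but with opposite
#' effect direction).
#'
#' @param ewas_A,ewas_B `ewas_result`s of disease A resp. B vs control over
#'   the same site universe.
#' @param p_cutoff Genome-wide DMC p cutoff (default: Bonferroni at 0.05
#'   over the tested sites).
#' @param delta_cutoff `|delta_beta|` cutoff for DMC calling.
#' @param alpha Family-wise level used to derive the sharing cutoff.
#' @param reference_disease `"A"` or `"B"`: whose DMC count anchors the
#'   sharing cutoff (the convention is the larger, better-powered EWAS).
#' @return A list: `dmcs_A`, `dmcs_B` (dmc_sets), `shared_from_A`,
#'   `shared_from_B`, `shared` (combined `shared_dmc_set`), `unique_A`,
#'   `unique_B`, `labels_A`, `labels_B` (per-DMC label tibbles), and
#'   `shared_p_cutoff`.
#' @export
classify_cross_disease <- function(ewas_A, ewas_B,
                                   p_cutoff = bonferroni_threshold(0.05, nrow(ewas_A)),
                                   delta_cutoff = 0.05,
                                   alpha = 0.05,
                                   reference_disease = c("A", "B")) {
  reference_disease <- match.arg(reference_disease)
  dmcs_A <- call_dmcs(ewas_A, p_cutoff, delta_cutoff)
  dmcs_B <- call_dmcs(ewas_B, p_cutoff, delta_cutoff)
  n_ref <- if (reference_disease == "A") nrow(dmcs_A) else nrow(dmcs_B)
  if (n_ref == 0) abort("reference disease has no DMCs; sharing cutoff undefined")
  shared_p_cutoff <- bonferroni_threshold(alpha, n_ref)

  shared_from_A <- classify_shared(dmcs_A, ewas_B, shared_p_cutoff)
  shared_from_B <- classify_shared(dmcs_B, ewas_A, shared_p_cutoff)
  unique_A <- classify_unique(dmcs_A, ewas_B)
  unique_B <- classify_unique(dmcs_B, ewas_A)

  label_one <- function(dmcs, ewas_other, shared_sites, unique_sites) {
    pair_with_other(dmcs, ewas_other) |>
      mutate(label = dplyr::case_when(
        .data$site_id %in% shared_sites ~ "shared",
        .data$site_id %in% unique_sites ~ "unique",
        .data$p_other < shared_p_cutoff ~ "discordant",
        TRUE ~ "indeterminate"
      ))
  }
  list(
    dmcs_A = dmcs_A, dmcs_B = dmcs_B,
    shared_from_A = shared_from_A, shared_from_B = shared_from_B,
    shared = combine_shared_sets(shared_from_A, shared_from_B),
    unique_A = unique_A, unique_B = unique_B,
    labels_A = label_one(dmcs_A, ewas_B, shared_from_A$site_id, unique_A$site_id),
    labels_B = label_one(dmcs_B, ewas_A, shared_from_B$site_id, unique_B$site_id),
    shared_p_cutoff = shared_p_cutoff,
    p_cutoff = p_cutoff, delta_cutoff = delta_cutoff
  )
}

#' Direct case-case differential methylation between the two diseases
#'
#' Runs the covariate-adjusted EWAS with disease A as case and disease B as
#' reference (`delta_beta = mean(A) - mean(B)`), calls DMCs at the
#' genome-wide Bonferroni cutoff and `|delta_beta| > delta_cutoff`, and
#' reports what fraction of the case-case DMCs are also DMCs in *both*
#' case-control comparisons (quantitative differences at otherwise shared
#' sites).
#'
#' @inheritParams run_ewas
#' @param dmcs_A,dmcs_B Optional `dmc_set`s from the two case-control EWASs
#'   used for the overlap bookkeeping.
#' @param delta_cutoff `|delta_beta|` cutoff.
#' @param alpha Family-wise level for the Bonferroni cutoff.
#' @return List: `ewas` (`ewas_result`), `dmcs` (`dmc_set`), and `overlap`
#'   (one-row tibble: `n_case_case`, `n_in_both_case_control`,
#'   `pct_in_both`).
#' @export
case_case_comparison <- function(beta, sheet, proportions = NULL,
                                 dmcs_A = NULL, dmcs_B = NULL,
                                 delta_cutoff = 0.05, alpha = 0.05,
                                 covariates = c("sex", "age")) {
  ew <- run_ewas(beta, sheet, case_group = "disease_A",
                 reference_group = "disease_B",
                 proportions = proportions, covariates = covariates)
  dm <- call_dmcs(ew, bonferroni_threshold(alpha, nrow(ew)), delta_cutoff)
  overlap <- NULL
  if (!is.null(dmcs_A) && !is.null(dmcs_B)) {
    in_both <- intersect(dm$site_id, intersect(dmcs_A$site_id, dmcs_B$site_id))
    overlap <- tibble(
      n_case_case = nrow(dm),
      n_in_both_case_control = length(in_both),
      pct_in_both = if (nrow(dm) > 0) round(100 * length(in_both) / nrow(dm)) else NA_real_
    )
  }
  list(ewas = ew, dmcs = dm, overlap = overlap)
}
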