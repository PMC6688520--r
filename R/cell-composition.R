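#' Select cell-type discriminating CpG sites from a reference
#'
#' Ranks sites, per cell type, by the gap between that type's methylation and
#' the nearest other type's methylation, and returns the union of the top
#' `n_per_type` most hypermethylated and top `n_per_type` most hypomethylated
#' sites per type (deduplicated). These marker sites are the basis on which
#' cell proportions are projected.
#'
#' @param reference A `reference_profiles` matrix (sites x cell types).
#' @param n_per_type Markers per direction per cell type (default 50, a
#'   common convention; the choice is recorded in the run configuration).
#' @return Character vector of selected site ids.
#' @export
select_discriminating_sites <- function(reference, n_per_type = 50) {
  if (n_per_type < 1) abort("n_per_type must be >= 1")
  R <- unclass(reference)
  k <- ncol(R)
  if (k < 2) abort("need >= 2 cell types")
  if (2 * n_per_type > nrow(R)) abort("fewer sites than requested markers")
  # signed gap to nearest other type, per site per type
  picked <- character(0)
  for (ct in seq_len(k)) {
    others <- R[, -ct, drop = FALSE]
    gap_up <- R[, ct] - apply(others, 1, max)   # > 0: hyper vs all others
    gap_dn <- apply(others, 1, min) - R[, ct]   # > 0: hypo vs all others
    if (all(gap_up <= 0) && all(gap_dn <= 0)) {
      abort(paste0("non-discriminable reference: cell type '", colnames(R)[ct],
                   "' has no site separating it from the other types"))
    }
    hyper <- rownames(R)[order(gap_up, decreasing = TRUE)][seq_len(n_per_type)]
    hypo <- rownames(R)[order(gap_dn, decreasing = TRUE)][seq_len(n_per_type)]
    picked <- c(picked, hyper, hypo)
  }
  unique(picked)
}

#' Estimate cell-type proportions by constrained projection
#'
#' For each sample, solves the constrained least-squares problem
#' `min_w || beta_sample - R w ||^2` subject to `w >= 0` and `sum(w) <= 1`,
#' where `R` is the reference restricted to the selected marker sites
#' (reference-based deconvolution of whole-blood methylomes). The sum
#' constraint is an inequality, not an equality, and estimates are not
#' renormalized: renormalization would make the proportion covariates
#' exactly collinear downstream.
#'
#' @param beta A [beta_matrix()] of study samples.
#' @param reference A `reference_profiles` matrix.
#' @param sites Marker site ids (default: [select_discriminating_sites()]
#'   on the reference); must be present in both matrices.
#' @return A `cell_proportions` tibble: `sample_id` plus one column per cell
#'   type; attribute `sites` records the marker panel used.
#' @export
estimate_proportions <- function(beta, reference,
                                 sites = select_discriminating_sites(reference)) {
  missing_b <- setdiff(sites, rownames(beta))
  missing_r <- setdiff(sites, rownames(reference))
  if (length(missing_b) > 0 || length(missing_r) > 0) {
    abort(paste0("marker site(s) absent from ",
                 if (length(missing_b) > 0) "beta matrix" else "reference", ": ",
                 paste(head(c(missing_b, missing_r), 5), collapse = ", ")))
  }
  R <- unclass(reference)[sites, , drop = FALSE]
  qrR <- qr(R)
  if (qrR$rank < ncol(R)) {
    dropped <- colnames(R)[-qrR$pivot[seq_len(qrR$rank)]]
    abort(paste0("reference is rank-deficient on the marker panel; collinear cell type(s): ",
                 paste(dropped, collapse = ", ")))
  }
  B <- unclass(beta)[sites, , drop = FALSE]
  k <- ncol(R)
  Dmat <- crossprod(R)
  # constraints: I w >= 0  and  -1' w >= -1
  Amat <- cbind(diag(k), -1)
  bvec <- c(rep(0, k), -1)
  W <- vapply(seq_len(ncol(B)), function(j) {
    sol <- quadprog::solve.QP(Dmat, crossprod(R, B[, j]), Amat, bvec)
    pmax(sol$solution, 0)
  }, numeric(k))
  out <- dplyr::bind_cols(
    tibble(sample_id = colnames(B)),
    as_tibble(setNames(as.data.frame(t(W)), colnames(R)))
  )
  structure(out, sites = sites,
            class = c("cell_proportions", class(out)))
}

cell_type_columns <- function(proportions) {
  setdiff(names(proportions), "sample_id")
}
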