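#' Tidy / glance methods for methcross result objects
#'
#' `tidy()` returns the per-unit table (per site, per sample, per category);
#' `glance()` returns a one-row model-level summary.
#'
#' @param x A methcross result object.
#' @param ... Unused.
#' @return A tibble.
#' @name methcross-tidiers
NULL

#' @rdname methcross-tidiers
#' @method tidy ewas_result
#' @export
tidy.ewas_result <- function(x, ...) as_tibble(x)

#' @rdname methcross-tidiers
#' @method glance ewas_result
#' @export
glance.ewas_result <- function(x, ...) {
  tibble(
    case_group = attr(x, "case_group"),
    reference_group = attr(x, "reference_group"),
    n_case = attr(x, "n_case"), n_reference = attr(x, "n_reference"),
    n_sites = nrow(x),
    cell_adjusted = isTRUE(attr(x, "cell_adjusted")),
    model_scale = attr(x, "model_scale"),
    lambda = stats::median(stats::qchisq(as_tibble(x)$p, df = 1, lower.tail = FALSE)) /
      stats::qchisq(0.5, df = 1)
  )
}

#' @rdname methcross-tidiers
#' @method tidy dmc_set
#' @export
tidy.dmc_set <- function(x, ...) as_tibble(x)

#' @rdname methcross-tidiers
#' @method glance dmc_set
#' @export
glance.dmc_set <- function(x, ...) {
  dirs <- summarize_directions(x)
  tibble(
    case_group = attr(x, "case_group") %||% NA_character_,
    reference_group = attr(x, "reference_group") %||% NA_character_,
    n_dmcs = nrow(x), n_tested = attr(x, "n_tested"),
    p_cutoff = attr(x, "p_cutoff"),
    p_cutoff_display = format_threshold(attr(x, "p_cutoff")),
    delta_cutoff = attr(x, "delta_cutoff"),
    n_hypo = dirs$n_hypo, n_hyper = dirs$n_hyper,
    pct_hypo = dirs$pct_hypo, pct_hyper = dirs$pct_hyper
  )
}

#' @rdname methcross-tidiers
#' @method tidy mds_embedding
#' @export
tidy.mds_embedding <- function(x, ...) as_tibble(x)

#' @rdname methcross-tidiers
#' @method glance mds_embedding
#' @export
glance.mds_embedding <- function(x, ...) {
  ev <- attr(x, "eigenvalues")
  pos <- sum(pmax(ev, 0))
  tibble(
    n_samples = nrow(x), panel_size = length(attr(x, "panel")),
    eigenvalue_1 = ev[1], eigenvalue_2 = ev[2],
    var_explained_12 = if (pos > 0) sum(pmax(ev[1:2], 0)) / pos else NA_real_
  )
}

#' @rdname methcross-tidiers
#' @method tidy enrichment_result
#' @export
tidy.enrichment_result <- function(x, ...) as_tibble(x)

#' @rdname methcross-tidiers
#' @method glance enrichment_result
#' @export
glance.enrichment_result <- function(x, ...) {
  tibble(
    statistic = attr(x, "statistic"), p_overall = attr(x, "p_overall"),
    df = attr(x, "df"), n_categories = nrow(x),
    bonferroni_divisor = attr(x, "bonferroni_divisor"),
    exact_fallback = isTRUE(attr(x, "exact_fallback"))
  )
}

#' @rdname methcross-tidiers
#' @method tidy prediction_result
#' @export
tidy.prediction_result <- function(x, ...) x$predictions

#' @rdname methcross-tidiers
#' @method glance prediction_result
#' @export
glance.prediction_result <- function(x, ...) {
  tibble(
    comparison = x$comparison,
    n_iterations = nrow(x$auc_by_iteration),
    mean_auc = x$mean_auc, pooled_auc = x$pooled_auc,
    min_auc = min(x$auc_by_iteration$auc),
    max_auc = max(x$auc_by_iteration$auc)
  )
}
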