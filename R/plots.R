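#' Plot methods
#'
#' `autoplot()` methods return ggplot objects for the main result types:
#' an MDS embedding (optionally coloured by serology-stratified subgroup),
#' a volcano plot for an EWAS result, pooled ROC curves per CV iteration for
#' a prediction result, and an observed-vs-expected bar chart for an
#' enrichment result.
#'
#' @param object A methcross result object.
#' @param sheet Optional sample sheet used to colour MDS points by subgroup.
#' @param p_cutoff,delta_cutoff Thresholds drawn on the volcano plot.
#' @param ... Unused.
#' @return A `ggplot` object.
#' @name methcross-plots
NULL

#' @rdname methcross-plots
#' @method autoplot mds_embedding
#' @export
autoplot.mds_embedding <- function(object, sheet = NULL, ...) {
  df <- as_tibble(object)
  if (!is.null(sheet)) {
    sheet <- validate_sample_sheet(sheet)
    df <- left_join(df, sheet[, c("sample_id", "group", "serology")], by = "sample_id") |>
      mutate(subgroup = dplyr::case_when(
        .data$group == "disease_B" & .data$serology == "positive" ~ "disease_B seropositive",
        .data$group == "disease_B" ~ "disease_B seronegative",
        TRUE ~ .data$group
      ))
    p <- ggplot2::ggplot(df, ggplot2::aes(.data$dim1, .data$dim2,
                                          colour = .data$subgroup))
  } else {
    p <- ggplot2::ggplot(df, ggplot2::aes(.data$dim1, .data$dim2))
  }
  p + ggplot2::geom_point(alpha = 0.8) +
    ggplot2::labs(x = "Coordinate 1", y = "Coordinate 2") +
    ggplot2::theme_minimal()
}

#' @rdname methcross-plots
#' @method autoplot ewas_result
#' @export
autoplot.ewas_result <- function(object,
                                 p_cutoff = bonferroni_threshold(0.05, nrow(object)),
                                 delta_cutoff = 0.05, ...) {
  df <- as_tibble(object) |>
    mutate(dmc = .data$p < p_cutoff & abs(.data$delta_beta) > delta_cutoff)
  ggplot2::ggplot(df, ggplot2::aes(.data$delta_beta, -log10(.data$p),
                                   colour = .data$dmc)) +
    ggplot2::geom_point(size = 0.4, alpha = 0.5) +
    ggplot2::geom_hline(yintercept = -log10(p_cutoff), linetype = 2) +
    ggplot2::geom_vline(xintercept = c(-delta_cutoff, delta_cutoff), linetype = 2) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey50", `TRUE` = "firebrick"),
                                 guide = "none") +
    ggplot2::labs(
      x = expression(Delta * beta ~ "(case - reference)"),
      y = expression(-log[10] ~ p),
      title = paste0(attr(object, "case_group"), " vs ", attr(object, "reference_group"))
    ) +
    ggplot2::theme_minimal()
}

#' @rdname methcross-plots
#' @method autoplot prediction_result
#' @export
autoplot.prediction_result <- function(object, ...) {
  curves <- object$predictions |>
    group_by(.data$iteration) |>
    dplyr::group_modify(~ roc_auc(.x$score, .x$label == "case")$roc) |>
    ungroup() |>
    mutate(iteration = factor(.data$iteration))
  ggplot2::ggplot(curves, ggplot2::aes(.data$fpr, .data$tpr,
                                       colour = .data$iteration)) +
    ggplot2::geom_step(direction = "hv") +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 3, colour = "grey60") +
    ggplot2::labs(x = "False positive rate", y = "True positive rate",
                  title = object$comparison,
                  subtitle = sprintf("mean AUC = %.3f", object$mean_auc)) +
    ggplot2::theme_minimal()
}

#' @rdname methcross-plots
#' @method autoplot enrichment_result
#' @export
autoplot.enrichment_result <- function(object, ...) {
  df <- as_tibble(object) |>
    tidyr::pivot_longer(c("observed", "expected"),
                        names_to = "kind", values_to = "count")
  ggplot2::ggplot(df, ggplot2::aes(.data$category, .data$count,
                                   fill = .data$kind)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = NULL, y = "CpG sites", fill = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}
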