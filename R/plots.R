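# Figure helpers: funnel progression and QC plots.

#' Funnel progression plot
#'
#' Percentage of peptides surviving each decision-tree stage, starting at
#' 100% of the identified peptides, one line per sample.
#'
#' @param funnels Tibble of one or more [funnel()] rows.
#' @return A ggplot object.
#' @export
plot_funnel <- function(funnels) {
  long <- funnels |>
    dplyr::transmute(
      sample_id = .data$sample_id,
      identified = 100,
      length = .data$pct_pass_length,
      binding = .data$pct_pass_binding,
      selected = .data$pct_selected
    ) |>
    tidyr::pivot_longer(-"sample_id", names_to = "stage",
                        values_to = "percent") |>
    dplyr::mutate(stage = factor(.data$stage, levels = c(
      "identified", "length", "binding", "selected")))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$stage, y = .data$percent,
                                     group = .data$sample_id,
                                     colour = .data$sample_id)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(x = NULL, y = "% of identified peptides",
                  colour = "sample") +
    ggplot2::theme_minimal()
}

#' Ion mobility vs m/z scatter colored by mobility group
#'
#' @param records Peptide record tibble.
#' @param groups Result of [mobility_groups()] on the same records.
#' @return A ggplot object.
#' @export
plot_mobility <- function(records, groups) {
  df <- tibble::tibble(
    mz = records$mz, ion_mobility = records$ion_mobility,
    group = groups$labels
  )
  df <- df[!is.na(df$group), , drop = FALSE]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$mz, y = .data$ion_mobility,
                                   colour = .data$group)) +
    ggplot2::geom_point(alpha = 0.4, size = 0.8) +
    ggplot2::labs(x = "m/z (Th)", y = "1/K0 (Vs/cm2)", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Length or charge histogram bar plot
#'
#' @param histogram A histogram tibble (`value`, `count`) from
#'   [compute_distributions()].
#' @param xlab Axis label.
#' @return A ggplot object.
#' @export
plot_histogram <- function(histogram, xlab = "value") {
  ggplot2::ggplot(histogram, ggplot2::aes(x = .data$value, y = .data$count)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = xlab, y = "peptide count") +
    ggplot2::theme_minimal()
}
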