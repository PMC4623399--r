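#' MA-style plot of a two-library DE contrast
#'
#' Mean normalized abundance (x, log10) against log2 fold change (y), with
#' up/down calls highlighted. Infinite fold changes (extinction in one
#' library) are drawn at the plot's edge.
#'
#' @param de A [call_de_table()] result.
#' @return A ggplot object.
#' @export
plot_ma <- function(de) {
  stopifnot(inherits(de, "de_results"))
  n1 <- attr(de, "n1"); n2 <- attr(de, "n2")
  d <- de |>
    dplyr::mutate(
      mean_norm = (.data$x / n1 + .data$y / n2) / 2 * 1e6,
      log2fc_plot = pmax(pmin(.data$log2fc, 15), -15)
    )
  ggplot2::ggplot(d, ggplot2::aes(x = .data$mean_norm,
                                  y = .data$log2fc_plot,
                                  colour = .data$call)) +
    ggplot2::geom_point(size = 0.4, alpha = 0.6) +
    ggplot2::scale_x_log10() +
    ggplot2::scale_colour_manual(values = c(up = "#d73027", down = "#4575b4",
                                            ns = "grey60")) +
    ggplot2::labs(x = "mean normalized abundance (reads per million)",
                  y = "log2 fold change (OE / WT)", colour = NULL) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @rdname plot_ma
#' @param object A `de_results` object (autoplot method).
#' @param ... Ignored.
#' @exportS3Method ggplot2::autoplot
autoplot.de_results <- function(object, ...) plot_ma(object)

#' Bar chart of up/down DE counts per stratum
#'
#' @param summary A [de_summary_counts()] tibble.
#' @param by Column used on the x axis (defaults to the first
#'   stratification column, or a single bar when none).
#' @return A ggplot object.
#' @export
plot_de_counts <- function(summary, by = NULL) {
  stopifnot(is.data.frame(summary))
  by <- by %||% setdiff(names(summary), c("n_up", "n_down", "n_tested"))[1]
  d <- summary |>
    tidyr::pivot_longer(c("n_up", "n_down"), names_to = "direction",
                        values_to = "n") |>
    dplyr::mutate(direction = dplyr::if_else(.data$direction == "n_up",
                                             "up", "down"))
  xvar <- if (is.na(by)) "direction" else by
  ggplot2::ggplot(d, ggplot2::aes(x = factor(.data[[xvar]]), y = .data$n,
                                  fill = .data$direction)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::scale_fill_manual(values = c(up = "#d73027", down = "#4575b4")) +
    ggplot2::labs(x = NULL, y = "differentially expressed features",
                  fill = NULL) +
    ggplot2::theme_minimal()
}

#' Mean +/- SD bars for an assay panel
#'
#' Grouped bar chart of replicate summaries (one panel per analyte) with SD
#' error bars and significance stars from [compare_groups()] if supplied.
#'
#' @param data Long assay tibble with `value`, `genotype`, `timepoint` and
#'   an analyte column (`analyte` or `metabolite`).
#' @return A ggplot object.
#' @export
plot_assay_panel <- function(data) {
  stopifnot(is.data.frame(data))
  avar <- intersect(c("analyte", "metabolite"), names(data))[1]
  if (is.na(avar)) abort("`data` needs an `analyte` or `metabolite` column.")
  s <- summarize_assay(data, by = c(avar, "genotype", "timepoint"))
  ggplot2::ggplot(s, ggplot2::aes(x = .data$timepoint, y = .data$mean,
                                  fill = .data$genotype)) +
    ggplot2::geom_col(position = ggplot2::position_dodge(0.9), width = 0.8) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$mean - .data$sd,
                                        ymax = .data$mean + .data$sd),
                           position = ggplot2::position_dodge(0.9),
                           width = 0.25) +
    ggplot2::facet_wrap(avar, scales = "free_y") +
    ggplot2::labs(x = NULL, y = "mean ± SD", fill = NULL) +
    ggplot2::theme_minimal()
}

#' Tile display of a category-by-timepoint enrichment matrix
#'
#' Median log2 fold change per category and timepoint as a false-color tile
#' map, with significant cells outlined — the tabular PageMan-style
#' condensed display.
#'
#' @param results Row-bound [enrich_categories()] outputs with `timepoint`.
#' @return A ggplot object.
#' @export
plot_enrichment_matrix <- function(results) {
  stopifnot(is.data.frame(results),
            all(c("category", "timepoint", "median_log2fc", "significant")
                %in% names(results)))
  ggplot2::ggplot(results,
                  ggplot2::aes(x = factor(.data$timepoint),
                               y = .data$category,
                               fill = .data$median_log2fc)) +
    ggplot2::geom_tile(ggplot2::aes(colour = .data$significant),
                       linewidth = 0.6) +
    ggplot2::scale_fill_gradient2(low = "#4575b4", mid = "white",
                                  high = "#d73027", midpoint = 0) +
    ggplot2::scale_colour_manual(values = c(`TRUE` = "black",
                                            `FALSE` = NA)) +
    ggplot2::labs(x = "timepoint", y = NULL, fill = "median log2 FC",
                  colour = "P < 0.01") +
    ggplot2::theme_minimal()
}
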