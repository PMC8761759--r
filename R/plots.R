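# ggplot2 figures mirroring the standard presentation of these analyses:
# per-site density boxplots on a log scale, paired pre/post line plots,
# and per-region concordance dot plots.

#' Boxplots of densities per tissue site
#'
#' One box per tissue site, faceted by subset and compartment, on a log10
#' scale. Zero densities are replaced by `zero_substitute` (default 0.5
#' cells/mm^2) for display only - statistics never see substituted values.
#'
#' @param densities Tidy density table (e.g. [cohort_densities()]).
#' @param zero_substitute Display value replacing zeros on the log scale.
#' @return A ggplot object.
#' @export
plot_site_densities <- function(densities, zero_substitute = 0.5) {
  d <- densities |>
    dplyr::filter(!is.na(.data$density_per_mm2),
                  .data$compartment != "background") |>
    dplyr::mutate(display_density = dplyr::if_else(
      .data$density_per_mm2 == 0, zero_substitute, .data$density_per_mm2))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$tissue_site,
                                  y = .data$display_density)) +
    ggplot2::geom_boxplot(outlier.size = 0.6) +
    ggplot2::scale_y_log10() +
    ggplot2::facet_grid(compartment ~ subset) +
    ggplot2::labs(x = NULL, y = "cells/mm²") +
    ggplot2::theme_bw() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}

#' Paired pre/post density line plot
#'
#' One line per patient connecting pre- and post-treatment densities,
#' faceted by subset and compartment, log10 scale with zero substitution
#' for display.
#'
#' @param densities Tidy density table with `patient_id`, `timepoint`.
#' @param pre,post Timepoint labels.
#' @param zero_substitute Display value replacing zeros.
#' @return A ggplot object.
#' @export
plot_paired_changes <- function(densities,
                                pre = "metastasis_pre_chemo",
                                post = "metastasis_post_chemo",
                                zero_substitute = 0.5) {
  d <- average_replicates(
    dplyr::filter(densities, .data$timepoint %in% c(pre, post),
                  !is.na(.data$density_per_mm2))) |>
    dplyr::mutate(
      timepoint = factor(.data$timepoint, levels = c(pre, post)),
      display_density = dplyr::if_else(.data$density_per_mm2 == 0,
                                       zero_substitute,
                                       .data$density_per_mm2))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$timepoint,
                                  y = .data$display_density,
                                  group = .data$patient_id)) +
    ggplot2::geom_line(alpha = 0.6) +
    ggplot2::geom_point(size = 1) +
    ggplot2::scale_y_log10() +
    ggplot2::facet_grid(compartment ~ subset) +
    ggplot2::labs(x = NULL, y = "cells/mm²") +
    ggplot2::theme_bw()
}

#' Plot a concordance result
#'
#' Region densities (dots, the four regions of a sample connected) over
#' samples ordered by mean density, with the quartile cutpoints as
#' horizontal lines; misclassified regions are highlighted.
#'
#' @param object A `concordance_result`.
#' @param zero_substitute Display value replacing zeros on the log scale.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot concordance_result
#' @export
autoplot.concordance_result <- function(object, zero_substitute = 5, ...) {
  ord <- object$samples |>
    dplyr::arrange(.data$mean_density) |>
    dplyr::mutate(rank = dplyr::row_number())
  d <- object$regions |>
    dplyr::left_join(dplyr::select(ord, "sample_id", "rank"),
                     by = "sample_id") |>
    dplyr::mutate(display_density = dplyr::if_else(
      .data$density_per_mm2 == 0, zero_substitute, .data$density_per_mm2))
  cuts <- tibble(cut = pmax(object$cutpoints, zero_substitute))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$rank,
                                  y = .data$display_density)) +
    ggplot2::geom_line(ggplot2::aes(group = .data$sample_id),
                       alpha = 0.4) +
    ggplot2::geom_point(ggplot2::aes(color = .data$correct), size = 1) +
    ggplot2::geom_hline(data = cuts,
                        ggplot2::aes(yintercept = .data$cut),
                        linetype = "dashed") +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "sample (ordered by mean region density)",
                  y = "cells/mm²",
                  title = sprintf("%s: correct classification rate %.1f%%",
                                  object$subset, object$correct_rate),
                  color = "correct quartile") +
    ggplot2::theme_bw()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
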