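# ggplot2 displays for the main result types.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a chromatogram
#'
#' @param object A [extract_xic()] chromatogram.
#' @param ... Ignored.
#' @return A ggplot.
#' @export
autoplot.chromatogram <- function(object, ...) {
  ggplot2::ggplot(tibble::as_tibble(object),
                  ggplot2::aes(x = .data$rt, y = .data$intensity)) +
    ggplot2::geom_line() +
    ggplot2::labs(
      x = "retention time (min)", y = "intensity",
      title = sprintf("XIC m/z %.4f (+/- %g ppm)", attr(object, "mz"),
                      attr(object, "ppm"))) +
    ggplot2::theme_minimal()
}

#' Plot an ion image
#'
#' @param object An [extract_ion_image()] result.
#' @param ... Ignored.
#' @return A ggplot raster of per-pixel intensity.
#' @export
autoplot.ion_image <- function(object, ...) {
  ggplot2::ggplot(tibble::as_tibble(object),
                  ggplot2::aes(x = .data$x, y = .data$y,
                               fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(na.value = "grey90") +
    ggplot2::coord_fixed() +
    ggplot2::labs(title = sprintf("m/z %.4f (+/- %g ppm)",
                                  attr(object, "mz"), attr(object, "ppm")),
                  fill = "intensity") +
    ggplot2::theme_minimal()
}

#' Bar plot of corrected isotopologue distributions
#'
#' Mirrors the familiar relative-abundance-by-isotopologue display: one bar
#' per isotopologue index, faceted or coloured by group.
#'
#' @param corrected Long tibble from [correct_isotopologues()].
#' @param design Optional [study_design()] for group colouring.
#' @param lipid Lipid to display (default: first in the table).
#' @return A ggplot.
#' @export
plot_isotopologues <- function(corrected, design = NULL, lipid = NULL) {
  lipid <- lipid %||% corrected$lipid[1]
  df <- dplyr::filter(corrected, .data$lipid == !!lipid)
  if (!is.null(design)) df <- dplyr::left_join(df, design, by = "sample")
  df$pct <- 100 * df$fraction
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$n, y = .data$pct))
  if (!is.null(design)) {
    df_mean <- df |>
      dplyr::group_by(.data$group, .data$n) |>
      dplyr::summarise(pct = mean(.data$pct), .groups = "drop")
    p <- ggplot2::ggplot(df_mean,
                         ggplot2::aes(x = .data$n, y = .data$pct)) +
      ggplot2::facet_wrap(~group)
  }
  p + ggplot2::geom_col() +
    ggplot2::labs(x = "isotopologue (M+n)",
                  y = "relative abundance (%)", title = lipid) +
    ggplot2::theme_minimal()
}

#' Percent-deuteration heat map
#'
#' @param heatmap Wide matrix from [deuteration_matrix()].
#' @return A ggplot tile map (lipids x samples).
#' @export
plot_deuteration_heatmap <- function(heatmap) {
  long <- tidyr::pivot_longer(heatmap, -"lipid", names_to = "sample",
                              values_to = "pct")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$sample, y = .data$lipid,
                                     fill = .data$pct)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(limits = c(0, 100)) +
    ggplot2::labs(fill = "% deuteration") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}
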