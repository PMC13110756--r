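# Mass spectrometry imaging: isotopologue ion images, internal-standard
# normalisation, and region-level statistics.

#' Construct an MSI run
#'
#' @param pixels Data frame with one row per pixel: integer grid coordinates
#'   `x`, `y` (unique pairs) and list-columns `mz`, `intensity` holding the
#'   centroided spectrum of each pixel.
#' @param pitch Pixel pitch in micrometres (default 30).
#' @param id Run (section/sample) identifier.
#' @param polarity Ionisation mode.
#' @return An object of class `msi_run`.
#' @export
msi_run <- function(pixels, pitch = 30, id = "section", polarity = "positive") {
  stopifnot(all(c("x", "y", "mz", "intensity") %in% names(pixels)),
            pitch > 0)
  if (anyDuplicated(pixels[c("x", "y")])) stop("duplicate pixel coordinates")
  structure(list(pixels = tibble::as_tibble(pixels), pitch = pitch, id = id,
                 polarity = polarity),
            class = "msi_run")
}

#' @export
print.msi_run <- function(x, ...) {
  cat("<msi_run> ", x$id, ": ", nrow(x$pixels), " pixels, ",
      x$pitch, " um pitch, ", x$polarity, " mode\n", sep = "")
  invisible(x)
}

#' Extract an isotopologue ion image
#'
#' Per pixel, sums centroid intensities within a symmetric ppm window of the
#' requested m/z. Grid positions inside the bounding box that carry no
#' spectrum are reported as missing (`NA`), not zero.
#'
#' @param run An [msi_run()].
#' @param mz Window centre m/z.
#' @param ppm Half-width in ppm (default 15).
#' @return A tibble of class `ion_image`: `x`, `y`, `value` over the full
#'   bounding-box grid; attributes `mz`, `ppm`, `pitch`, `id`.
#' @export
extract_ion_image <- function(run, mz, ppm = 15) {
  stopifnot(inherits(run, "msi_run"), ppm > 0, mz > 0)
  half <- mz * ppm * 1e-6
  px <- run$pixels
  value <- purrr::map2_dbl(px$mz, px$intensity, function(m, i) {
    sel <- abs(m - mz) <= half
    if (any(sel)) sum(i[sel]) else 0
  })
  grid <- tidyr::expand_grid(x = seq(min(px$x), max(px$x)),
                             y = seq(min(px$y), max(px$y)))
  out <- dplyr::left_join(
    grid, tibble::tibble(x = px$x, y = px$y, value = value),
    by = c("x", "y"))
  attr(out, "mz") <- mz
  attr(out, "ppm") <- ppm
  attr(out, "pitch") <- run$pitch
  attr(out, "id") <- run$id
  class(out) <- c("ion_image", class(out))
  out
}

#' Per-pixel internal-standard normalisation
#'
#' Divides an analyte ion image by the image of a sprayed internal standard
#' pixel by pixel, cancelling spatially varying ionisation efficiency.
#' Pixels where the standard is zero or missing become missing (neither
#' zero nor infinite).
#'
#' @param image Analyte [extract_ion_image()].
#' @param standard Internal-standard image on the identical grid.
#' @return An `ion_image` of per-pixel ratios.
#' @export
normalize_to_standard <- function(image, standard) {
  if (nrow(image) != nrow(standard) ||
      !all(image$x == standard$x & image$y == standard$y)) {
    stop("analyte and standard images are on different pixel grids")
  }
  out <- image
  denom <- standard$value
  denom[!is.na(denom) & denom == 0] <- NA_real_
  out$value <- image$value / denom
  attr(out, "normalised_to") <- attr(standard, "mz")
  out
}

#' Read a region mask from a label TSV
#'
#' Tab-separated table with columns `x`, `y`, `region` over the pixel grid.
#'
#' @param path TSV path.
#' @return Tibble `x`, `y`, `region`.
#' @export
read_region_mask <- function(path) {
  df <- readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                        progress = FALSE)
  stopifnot(all(c("x", "y", "region") %in% names(df)))
  if (anyDuplicated(df[c("x", "y")])) stop("mask assigns a pixel twice")
  tibble::as_tibble(df)
}

#' Region-level summary of an ion image
#'
#' Mean intensity over the non-missing pixels of each labelled region,
#' with the contributing pixel count. Regions whose pixels are all missing
#' get `NA` with count 0.
#'
#' @param image An [extract_ion_image()] (possibly normalised).
#' @param mask Tibble `x`, `y`, `region` (see [read_region_mask()]).
#' @return Tibble: `region`, `mean`, `sd`, `n_pixels`.
#' @export
region_summary <- function(image, mask) {
  stopifnot(all(c("x", "y", "region") %in% names(mask)))
  dplyr::inner_join(tibble::as_tibble(image), mask, by = c("x", "y")) |>
    dplyr::group_by(.data$region) |>
    dplyr::summarise(
      mean = if (any(!is.na(.data$value))) {
        mean(.data$value, na.rm = TRUE)
      } else NA_real_,
      sd = stats::sd(.data$value, na.rm = TRUE),
      n_pixels = sum(!is.na(.data$value)),
      .groups = "drop")
}

#' Region-level group statistics across samples
#'
#' One-way ANOVA with Tukey HSD post tests across the heavy-water groups,
#' run separately per region (and per isotopologue when an `n` column is
#' present). The statistical unit is the per-sample region mean (one value
#' per animal). Pairwise fold changes between group means are reported.
#'
#' @param summaries Long tibble with columns `sample`, `region`, `mean`
#'   (per-sample region means) and optionally `n` (isotopologue index).
#' @param design A [study_design()] tibble.
#' @param alpha Significance level for the Tukey flags (default 0.05).
#' @return List of class `msi_stats`: `anova` (per region x isotopologue:
#'   F, p) and `pairwise` (Tukey contrasts with `estimate`, `fold_change`,
#'   `p_adj`, `significant`).
#' @export
region_group_stats <- function(summaries, design, alpha = 0.05) {
  stopifnot(all(c("sample", "region", "mean") %in% names(summaries)))
  df <- dplyr::left_join(summaries, design, by = "sample") |>
    dplyr::filter(.data$group %in% LABELED_GROUPS)
  if (!"n" %in% names(df)) df$n <- 0L
  counts <- df |>
    dplyr::group_by(.data$region, .data$n, .data$group) |>
    dplyr::summarise(k = dplyr::n(), .groups = "drop")
  if (any(counts$k < 2)) {
    stop("insufficient replicates: every group needs >= 2 samples per region")
  }
  an_rows <- list()
  pw_rows <- list()
  groups <- df |>
    dplyr::group_by(.data$region, .data$n) |>
    dplyr::group_split()
  for (sub in groups) {
    sub$group <- factor(sub$group, levels = LABELED_GROUPS)
    sub$group <- droplevels(sub$group)
    fit <- stats::aov(mean ~ group, data = sub)
    an <- summary(fit)[[1]]
    an_rows[[length(an_rows) + 1]] <- tibble::tibble(
      region = sub$region[1], n = sub$n[1],
      f = an$`F value`[1], p = an$`Pr(>F)`[1])
    tk <- stats::TukeyHSD(fit)$group
    gm <- tapply(sub$mean, sub$group, mean)
    cons <- strsplit(rownames(tk), "-", fixed = TRUE)
    pw_rows[[length(pw_rows) + 1]] <- tibble::tibble(
      region = sub$region[1], n = sub$n[1], contrast = rownames(tk),
      estimate = tk[, "diff"],
      fold_change = purrr::map_dbl(cons, ~ gm[[.x[1]]] / gm[[.x[2]]]),
      p_adj = tk[, "p adj"],
      significant = tk[, "p adj"] < alpha)
  }
  structure(list(anova = dplyr::bind_rows(an_rows),
                 pairwise = dplyr::bind_rows(pw_rows)),
            class = "msi_stats")
}

#' @export
print.msi_stats <- function(x, ...) {
  cat("<msi_stats> ", nrow(x$anova), " region x isotopologue ANOVAs, ",
      sum(x$pairwise$significant), " significant Tukey contrasts\n", sep = "")
  invisible(x)
}
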