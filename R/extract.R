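# Extracted-ion chromatograms and isotopologue peak integration from
# centroided LC-MS runs.

#' Construct a centroided LC-MS run
#'
#' @param scans A data frame with one row per scan: `rt` (minutes, strictly
#'   increasing), `ms_level`, and list-columns `mz` and `intensity` (sorted
#'   ascending in m/z, intensities >= 0); MS2 rows may carry `precursor_mz`.
#' @param id Run identifier.
#' @param polarity `"positive"` or `"negative"`.
#' @return An object of class `centroid_run`.
#' @export
centroid_run <- function(scans, id = "run", polarity = "positive") {
  stopifnot(all(c("rt", "ms_level", "mz", "intensity") %in% names(scans)))
  if (nrow(scans) == 0) stop("empty run: no scans")
  if (is.unsorted(scans$rt, strictly = FALSE)) {
    stop("scan retention times must be non-decreasing")
  }
  if (!"precursor_mz" %in% names(scans)) scans$precursor_mz <- NA_real_
  structure(list(scans = tibble::as_tibble(scans), id = id,
                 polarity = polarity),
            class = "centroid_run")
}

#' @export
print.centroid_run <- function(x, ...) {
  cat("<centroid_run> ", x$id, ": ", nrow(x$scans), " scans (",
      sum(x$scans$ms_level == 1), " MS1), ", x$polarity, " mode\n", sep = "")
  invisible(x)
}

#' Extracted-ion chromatogram
#'
#' For every MS1 scan, sums centroid intensities within a symmetric ppm
#' window of the centre m/z; scans with no matching centroid contribute 0.
#'
#' @param run A [centroid_run()].
#' @param mz Window centre m/z.
#' @param ppm Half-width in ppm (default 10).
#' @return A tibble of class `chromatogram` with columns `rt`, `intensity`
#'   and attributes `mz` and `ppm`.
#' @export
extract_xic <- function(run, mz, ppm = 10) {
  stopifnot(inherits(run, "centroid_run"), ppm > 0, mz > 0)
  ms1 <- run$scans[run$scans$ms_level == 1, ]
  if (nrow(ms1) == 0) stop("empty run: no MS1 scans")
  half <- mz * ppm * 1e-6
  intensity <- purrr::map2_dbl(ms1$mz, ms1$intensity, function(m, i) {
    sel <- abs(m - mz) <= half
    if (any(sel)) sum(i[sel]) else 0
  })
  out <- tibble::tibble(rt = ms1$rt, intensity = intensity)
  attr(out, "mz") <- mz
  attr(out, "ppm") <- ppm
  class(out) <- c("chromatogram", class(out))
  out
}

#' Integrate a chromatographic peak near a reference retention time
#'
#' The apex is the maximum-intensity point with `|rt - rt_ref| <= rt_window`
#' (ties broken towards `rt_ref`). Peak bounds descend from the apex to the
#' nearest local minimum or below `baseline_frac * apex` on each side, and
#' the area is the trapezoidal integral over the bounds. Detection requires
#' the apex intensity to exceed a noise floor: by default 3x the median
#' non-zero intensity outside the rt window (fallback 1.0 when the outside
#' baseline is empty).
#'
#' @param chrom A [extract_xic()] chromatogram (or any tibble with `rt`,
#'   `intensity`).
#' @param rt_ref Reference retention time (minutes).
#' @param rt_window Half-window (minutes, default 0.1).
#' @param baseline_frac Bound-stop fraction of apex (default 0.01).
#' @param threshold Absolute detection floor; `NULL` for the default rule.
#' @return One-row tibble: `area`, `apex_rt`, `apex_intensity`, `detected`.
#' @export
integrate_peak <- function(chrom, rt_ref, rt_window = 0.1,
                           baseline_frac = 0.01, threshold = NULL) {
  stopifnot(rt_window > 0)
  rt <- chrom$rt
  y <- chrom$intensity
  in_win <- which(abs(rt - rt_ref) <= rt_window)
  none <- tibble::tibble(area = 0, apex_rt = NA_real_, apex_intensity = 0,
                         detected = FALSE)
  if (length(in_win) == 0) return(none)
  ymax <- max(y[in_win])
  if (ymax <= 0) return(none)
  cand <- in_win[y[in_win] == ymax]
  apex <- cand[which.min(abs(rt[cand] - rt_ref))]
  if (is.null(threshold)) {
    outside <- y[-in_win]
    outside <- outside[outside > 0]
    threshold <- if (length(outside) > 0) 3 * stats::median(outside) else 1.0
  }
  floor_y <- baseline_frac * ymax
  left <- apex
  while (left > 1 && y[left - 1] <= y[left] && y[left] > floor_y) {
    left <- left - 1
  }
  right <- apex
  n <- length(y)
  while (right < n && y[right + 1] <= y[right] && y[right] > floor_y) {
    right <- right + 1
  }
  idx <- left:right
  area <- if (length(idx) > 1) {
    sum(diff(rt[idx]) * (utils::head(y[idx], -1) + utils::tail(y[idx], -1)) / 2)
  } else 0
  tibble::tibble(area = area, apex_rt = rt[apex], apex_intensity = ymax,
                 detected = ymax > threshold)
}

#' Extract a full isotopologue series for one target
#'
#' Runs [extract_xic()] and [integrate_peak()] for each isotopologue
#' `M+0..M+max_n` of a target, anchoring every integration window on the
#' M+0 apex retention time (falling back to the target's reference retention
#' time when M+0 is undetected).
#'
#' @param run A [centroid_run()].
#' @param target One row of a [lipid_targets()] tibble.
#' @param ppm m/z tolerance in ppm (default 10).
#' @param rt_window Retention-time half-window in minutes (default 0.1).
#' @param ... Passed to [integrate_peak()].
#' @return A tibble with one row per isotopologue: `sample`, `lipid`, `n`,
#'   `mz`, `area`, `apex_rt`, `detected`, `beyond_nh` (grid index past the
#'   accessible-hydrogen count).
#' @export
extract_series <- function(run, target, ppm = 10, rt_window = 0.1, ...) {
  stopifnot(nrow(target) == 1)
  grid <- isotopologue_mz(target$formula[[1]], target$adduct, 0:target$max_n)
  x0 <- extract_xic(run, grid$mz[1], ppm)
  p0 <- integrate_peak(x0, target$rt, rt_window, ...)
  anchor <- if (p0$detected) p0$apex_rt else target$rt
  rows <- purrr::map2_dfr(grid$n, grid$mz, function(n, mzv) {
    pk <- if (n == 0) p0 else {
      integrate_peak(extract_xic(run, mzv, ppm), anchor, rt_window, ...)
    }
    tibble::tibble(n = n, mz = mzv, area = pk$area, apex_rt = pk$apex_rt,
                   detected = pk$detected)
  })
  dplyr::mutate(rows,
                sample = run$id, lipid = target$lipid,
                beyond_nh = .data$n > target$n_h,
                .before = 1)
}

#' Extract isotopologue series for a whole cohort
#'
#' @param runs A list of [centroid_run()] objects (names or `$id` give the
#'   sample ids).
#' @param targets A [lipid_targets()] tibble.
#' @param ppm,rt_window Matching tolerances (defaults 10 ppm, 0.1 min).
#' @param ... Passed to [integrate_peak()].
#' @return Long tibble over sample x lipid x isotopologue.
#' @export
extract_cohort <- function(runs, targets, ppm = 10, rt_window = 0.1, ...) {
  purrr::map_dfr(runs, function(run) {
    purrr::map_dfr(seq_len(nrow(targets)), function(i) {
      extract_series(run, targets[i, ], ppm = ppm, rt_window = rt_window, ...)
    })
  })
}

#' Read a pre-extracted peak table
#'
#' Alternative entry point bypassing raw extraction: a long CSV with columns
#' `sample`, `lipid`, `n` (isotopologue index) and `area`; optional
#' `detected` (defaults to `area > 0`).
#'
#' @param path CSV file path.
#' @return Long tibble compatible with [correct_isotopologues()].
#' @export
read_peak_table <- function(path) {
  df <- readr::read_csv(path, comment = "#", show_col_types = FALSE,
                        progress = FALSE)
  need <- c("sample", "lipid", "n", "area")
  missing <- setdiff(need, names(df))
  if (length(missing) > 0) {
    stop("peak table lacks column(s): ", paste(missing, collapse = ", "))
  }
  if (!"detected" %in% names(df)) df$detected <- df$area > 0
  tibble::as_tibble(df)
}
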