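# Natural-abundance isotope correction on the deuterium tracer grid.
#
# At Orbitrap resolution some heavy isotopes (13C, 18O, ...) are not mass-
# resolved from the 2H isotopologue grid and leak signal into higher bins;
# fully resolved isotopes fall outside the narrow ppm extraction windows and
# are neither measured nor corrected. The correction matrix convolves the
# natural abundance of the unresolved isotopes for each tracer count, and a
# non-negative least-squares solve recovers the labeling distribution.

#' Mass-resolution model
#'
#' FWHM resolving power with a power-law mass dependence:
#' `R(m) = r_ref * (m / m_ref)^exponent` (Orbitrap-typical exponent -1/2),
#' so `FWHM(m) = m / R(m)`. Two peaks are treated as resolved when their
#' separation exceeds `criterion * FWHM`.
#'
#' @param r_ref Resolving power at the reference m/z (default 60000).
#' @param m_ref Reference m/z (default 200).
#' @param exponent Power-law exponent (default -0.5).
#' @param criterion Separation criterion in FWHM units (default 1).
#' @return An object of class `resolution_model`.
#' @export
#' @examples
#' res <- resolution_model(60000, 200)
#' fwhm(res, 760.5851)  # about 0.0247
resolution_model <- function(r_ref = 60000, m_ref = 200, exponent = -0.5,
                             criterion = 1.0) {
  stopifnot(r_ref > 0, m_ref > 0, criterion > 0)
  structure(list(r_ref = r_ref, m_ref = m_ref, exponent = exponent,
                 criterion = criterion),
            class = "resolution_model")
}

#' @rdname resolution_model
#' @param res A `resolution_model`.
#' @param mz m/z value(s).
#' @export
fwhm <- function(res, mz) {
  stopifnot(inherits(res, "resolution_model"))
  mz / (res$r_ref * (mz / res$m_ref)^res$exponent)
}

#' Partition heavy isotopes into resolved and unresolved sets
#'
#' A natural heavy isotope is "unresolved" from the deuterium grid when the
#' distance between its mass shift (relative to the lightest isotope) and the
#' nearest integer multiple of the tracer spacing (1.0062767 u) is below
#' `criterion * FWHM` at the ion's m/z. Only elements present in the formula
#' are considered.
#'
#' @param formula Neutral or ion formula (a [chem_formula] or string).
#' @param mz The m/z at which resolution is evaluated.
#' @param res A [resolution_model()].
#' @return A tibble with one row per heavy isotope: `element`, `mass_number`,
#'   `shift`, `grid_bin` (nearest tracer-grid bin), `grid_distance`, `fwhm`
#'   and `unresolved`.
#' @export
#' @examples
#' isotope_partition(lipid_formula("PC 34:1"), 760.5851, resolution_model())
isotope_partition <- function(formula, mz, res = resolution_model()) {
  formula <- as_chem_formula(formula)
  tbl <- isotope_table()
  present <- names(formula)[unclass(formula) > 0]
  present <- unique(sub("^D$", "H", present))
  spacing <- tracer_mass_shift()
  w <- fwhm(res, mz)
  out <- tbl |>
    dplyr::filter(.data$element %in% present) |>
    dplyr::group_by(.data$element) |>
    dplyr::mutate(shift = .data$mass - min(.data$mass)) |>
    dplyr::ungroup() |>
    dplyr::filter(.data$shift > 0)
  out |>
    dplyr::mutate(
      grid_bin = as.integer(round(.data$shift / spacing)),
      grid_distance = abs(.data$shift - .data$grid_bin * spacing),
      fwhm = w,
      unresolved = .data$grid_bin >= 1 &
        .data$grid_distance < res$criterion * w) |>
    dplyr::select("element", "mass_number", "shift", "grid_bin",
                  "grid_distance", "fwhm", "unresolved")
}

# per-atom probability vector over tracer-grid bins for one element,
# conditioned on the molecule being observed inside the extraction windows
# (resolved heavy isotopes are excluded and the remainder renormalised)
.atom_bin_distribution <- function(element, partition, max_bin) {
  tbl <- isotope_table()
  iso <- tbl[tbl$element == element, ]
  light_ab <- iso$abundance[1]
  part <- partition[partition$element == element & partition$unresolved, ]
  width <- max(max_bin, if (nrow(part) > 0) max(part$grid_bin) else 0)
  v <- numeric(width + 1)
  v[1] <- light_ab
  total <- light_ab
  if (nrow(part) > 0) {
    ab <- iso$abundance[match(part$mass_number, iso$mass_number)]
    for (j in seq_len(nrow(part))) {
      v[part$grid_bin[j] + 1] <- v[part$grid_bin[j] + 1] + ab[j]
      total <- total + ab[j]
    }
  }
  # normalise over light + unresolved (resolved isotopes fall outside the
  # extraction windows), THEN truncate: tail mass beyond max_bin leaks
  (v / total)[seq_len(max_bin + 1)]
}

# n-fold self-convolution of a per-atom vector, truncated to max_bin
.convolve_power <- function(v, n, max_bin) {
  out <- numeric(max_bin + 1)
  out[1] <- 1
  base <- v
  while (n > 0) {
    if (n %% 2 == 1) out <- .convolve_trunc(out, base, max_bin)
    n <- n %/% 2
    if (n > 0) base <- .convolve_trunc(base, base, max_bin)
  }
  out
}

.convolve_trunc <- function(a, b, max_bin) {
  full <- stats::convolve(a, rev(b), type = "open")
  full[full < 0] <- 0  # guard FFT round-off
  out <- full[seq_len(max_bin + 1)]
  out[is.na(out)] <- 0
  out
}

#' Natural-abundance isotopologue pattern on the tracer grid
#'
#' Exact polynomial convolution of the per-atom isotope distributions of all
#' atoms of elements with unresolved heavy isotopes, each isotope binned to
#' its nearest tracer-grid bin. Elements whose heavy isotopes are all
#' resolved contribute nothing (they are excluded from both measurement and
#' correction). The vector sums to 1 minus the mass truncated beyond
#' `max_bin` (reported as attribute `tail`).
#'
#' @param formula A [chem_formula] or string.
#' @param partition Output of [isotope_partition()]; by default everything
#'   unresolved (`NULL` means all heavy isotopes of present elements).
#' @param max_bin Last grid bin (default 20).
#' @return Numeric vector of length `max_bin + 1`, attribute `tail`.
#' @export
natural_pattern <- function(formula, partition = NULL, max_bin = 20L) {
  formula <- as_chem_formula(formula)
  counts <- unclass(formula)
  # deuterium atoms are isotopically pure; only the H count sees 2H abundance
  elements <- setdiff(names(counts)[counts > 0], "D")
  if (is.null(partition)) {
    tbl <- isotope_table()
    partition <- tbl |>
      dplyr::group_by(.data$element) |>
      dplyr::mutate(shift = .data$mass - min(.data$mass)) |>
      dplyr::ungroup() |>
      dplyr::filter(.data$shift > 0) |>
      dplyr::mutate(
        grid_bin = as.integer(round(.data$shift / tracer_mass_shift())),
        unresolved = .data$grid_bin >= 1)
  }
  out <- numeric(max_bin + 1)
  out[1] <- 1
  for (el in elements) {
    v <- .atom_bin_distribution(el, partition, max_bin)
    # element contributes nothing only when its atoms are purely bin-0
    if (abs(v[1] - 1) < 1e-15 && all(v[-1] == 0)) next
    out <- .convolve_trunc(out, .convolve_power(v, counts[[el]], max_bin),
                           max_bin)
  }
  structure(out, tail = max(0, 1 - sum(out)))
}

#' Build the isotope-correction matrix for a target
#'
#' Lower-triangular matrix whose column `j` is the natural-abundance pattern
#' of the molecule carrying `j` tracer deuteriums (formula with `j` hydrogens
#' replaced), shifted down to start at row `j`. An optional tracer purity
#' below 1 redistributes tracer atoms binomially towards lower bins.
#'
#' @param formula Neutral formula of the lipid (a [chem_formula] or string).
#' @param mz m/z of the monoisotopic ion, used to evaluate resolution.
#' @param res A [resolution_model()].
#' @param max_n Grid upper index (default 20; columns `0..max_n`).
#' @param purity Tracer isotopic purity in `[0, 1]` (default 1).
#' @return A `(max_n+1) x (max_n+1)` matrix of class `correction_matrix`
#'   with attributes `formula`, `partition` and `purity`.
#' @export
#' @examples
#' m <- correction_matrix(lipid_formula("PC 34:1"), mz = 760.5851)
#' m[1:4, 1:4]
correction_matrix <- function(formula, mz, res = resolution_model(),
                              max_n = 20L, purity = 1.0) {
  formula <- as_chem_formula(formula)
  stopifnot(max_n >= 1, purity > 0, purity <= 1)
  n_h <- unclass(formula)[["H"]]
  if (max_n > n_h) {
    stop("cannot build column for ", max_n, " tracer atoms: formula has only ",
         n_h, " hydrogens")
  }
  part <- isotope_partition(formula, mz, res)
  size <- max_n + 1L
  m <- matrix(0, size, size)
  patterns <- vector("list", size)
  for (j in 0:max_n) {
    fj <- unclass(formula)
    fj[["H"]] <- fj[["H"]] - j
    fj[["D"]] <- fj[["D"]] + j
    patterns[[j + 1]] <- as.numeric(
      natural_pattern(as_chem_formula(fj[fj > 0]), part, max_bin = max_n - j))
  }
  for (j in 0:max_n) {
    if (purity >= 1) {
      m[(j + 1):size, j + 1] <- patterns[[j + 1]]
    } else {
      # t of the j tracer positions actually carry 2H
      for (t in 0:j) {
        w <- stats::dbinom(t, j, purity)
        pat <- patterns[[t + 1]][seq_len(size - t)]
        m[(t + 1):size, j + 1] <- m[(t + 1):size, j + 1] + w * pat
      }
    }
  }
  structure(m, class = c("correction_matrix", "matrix", "array"),
            formula = format(formula), partition = part, purity = purity)
}

#' Lawson-Hanson non-negative least squares
#'
#' Solves `min ||A x - b||_2` subject to `x >= 0` by the active-set method.
#' Used to invert the correction matrix without producing negative
#' isotopologue fractions.
#'
#' @param a Matrix (m x n).
#' @param b Numeric vector (length m).
#' @param tol Dual-feasibility tolerance.
#' @return List with `x`, `residual` (2-norm) and `iterations`.
#' @export
nnls_solve <- function(a, b, tol = 1e-12) {
  a <- as.matrix(a)
  stopifnot(length(b) == nrow(a))
  n <- ncol(a)
  x <- numeric(n)
  passive <- logical(n)
  w <- crossprod(a, b - a %*% x)
  iter <- 0L
  max_iter <- 30L * n
  scale <- max(abs(w), 1)
  while (any(!passive) && max(w[!passive]) > tol * scale && iter < max_iter) {
    j <- which(!passive)[which.max(w[!passive])]
    passive[j] <- TRUE
    repeat {
      iter <- iter + 1L
      s <- numeric(n)
      ap <- a[, passive, drop = FALSE]
      s[passive] <- qr.solve(ap, b)
      if (all(s[passive] > tol)) break
      neg <- passive & s <= tol
      alpha <- min(x[neg] / (x[neg] - s[neg]))
      x <- x + alpha * (s - x)
      passive <- passive & x > tol
      x[!passive] <- 0
      if (iter >= max_iter) break
    }
    x <- s
    x[!passive] <- 0
    w <- crossprod(a, b - a %*% x)
  }
  resid <- sqrt(sum((b - a %*% x)^2))
  list(x = as.numeric(x), residual = resid, iterations = iter)
}

#' Correct one isotopologue series for natural isotope abundance
#'
#' Solves the non-negative least-squares problem `min ||M x - a||` over
#' labeling distributions `x >= 0` and normalises to fractions summing to 1.
#'
#' @param areas Raw integrated areas `a0..aN` (length must match the matrix).
#' @param matrix A [correction_matrix()].
#' @return A list of class `corrected_distribution`: `fraction` (length N+1,
#'   sums to 1), `residual` (relative to total raw signal), `total`
#'   (corrected signal on the raw-area scale).
#' @export
correct_series <- function(areas, matrix) {
  stopifnot(inherits(matrix, "correction_matrix"))
  if (length(areas) != nrow(matrix)) {
    stop("series length ", length(areas), " does not match matrix dimension ",
         nrow(matrix))
  }
  if (any(!is.finite(areas))) stop("non-finite areas in series")
  if (all(areas == 0)) stop("no signal: all isotopologue areas are zero")
  fit <- nnls_solve(unclass(matrix)[seq_along(areas), seq_along(areas)], areas)
  total_x <- sum(fit$x)
  structure(list(
    fraction = fit$x / total_x,
    residual = fit$residual / max(sum(areas), .Machine$double.eps),
    total = total_x),
    class = "corrected_distribution")
}

#' @export
print.corrected_distribution <- function(x, ...) {
  cat("<corrected_distribution> M+0..M+", length(x$fraction) - 1,
      "; x0 = ", signif(x$fraction[1], 4),
      "; percent deuteration = ", signif(100 * (1 - x$fraction[1]), 4),
      "%\n", sep = "")
  invisible(x)
}

#' Correct a long table of isotopologue series
#'
#' Data-frame-first wrapper around [correct_series()]: takes the long
#' extraction table (one row per sample, lipid and isotopologue index) and
#' appends natural-abundance-corrected fractions.
#'
#' @param data A data frame with columns `sample`, `lipid`, `n`, `area`.
#' @param targets A [lipid_targets()] tibble covering every lipid in `data`.
#' @param res A [resolution_model()].
#' @param purity Tracer purity passed to [correction_matrix()].
#' @return `data` with added columns `fraction` (corrected isotopologue
#'   fraction), `residual` and `corrected_total` (constant within a
#'   sample-lipid series).
#' @export
correct_isotopologues <- function(data, targets, res = resolution_model(),
                                  purity = 1.0) {
  stopifnot(all(c("sample", "lipid", "n", "area") %in% names(data)))
  mats <- list()
  for (i in seq_len(nrow(targets))) {
    mats[[targets$lipid[i]]] <- correction_matrix(
      targets$formula[[i]], mz = targets$mz0[i], res = res,
      max_n = targets$max_n[i], purity = purity)
  }
  data |>
    dplyr::group_by(.data$sample, .data$lipid) |>
    dplyr::group_modify(function(df, key) {
      m <- mats[[key$lipid]]
      if (is.null(m)) stop("no target for lipid '", key$lipid, "'")
      df <- dplyr::arrange(df, .data$n)
      if (all(df$area == 0)) {
        df$fraction <- NA_real_
        df$residual <- NA_real_
        df$corrected_total <- 0
      } else {
        cd <- correct_series(df$area, m)
        df$fraction <- cd$fraction
        df$residual <- cd$residual
        df$corrected_total <- cd$total
      }
      df
    }) |>
    dplyr::ungroup()
}
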