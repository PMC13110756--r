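# Shared fixture builders for the test suite. Everything is generated in
# code; no binary fixtures.

# a centroided run with a single analyte: Gaussian peak of given area at
# each (mz, rt); zero noise
make_simple_run <- function(peaks, rt_range = c(10, 12), dt = 0.01,
                            sigma = 0.05, id = "run") {
  rts <- seq(rt_range[1], rt_range[2], by = dt)
  mz_list <- vector("list", length(rts))
  int_list <- vector("list", length(rts))
  for (i in seq_along(rts)) {
    mzv <- numeric(0)
    itv <- numeric(0)
    for (p in seq_len(nrow(peaks))) {
      h <- peaks$area[p] / (sigma * sqrt(2 * pi))
      y <- h * exp(-(rts[i] - peaks$rt[p])^2 / (2 * sigma^2))
      if (y > h * 1e-4) {
        mzv <- c(mzv, peaks$mz[p])
        itv <- c(itv, y)
      }
    }
    o <- order(mzv)
    mz_list[[i]] <- mzv[o]
    int_list[[i]] <- itv[o]
  }
  centroid_run(tibble::tibble(rt = rts, ms_level = 1L, mz = mz_list,
                              intensity = int_list), id = id)
}

# independent brute-force isotopomer enumeration oracle: distribution of
# tracer-grid bins for a formula, enumerating every per-atom isotope choice
# of the elements with unresolved heavy isotopes. Exponential in atom count;
# keep formulas tiny.
enumeration_pattern <- function(formula, max_bin = 20) {
  tbl <- isotope_table()
  counts <- unclass(lipidflux::as_chem_formula(formula))
  spacing <- tracer_mass_shift()
  atom_opts <- list()
  for (el in names(counts)[counts > 0]) {
    if (el == "D") next
    iso <- tbl[tbl$element == el, ]
    shift <- iso$mass - iso$mass[1]
    bins <- as.integer(round(shift / spacing))
    for (a in seq_len(counts[[el]])) {
      atom_opts[[length(atom_opts) + 1]] <-
        list(bins = bins, probs = iso$abundance)
    }
  }
  out <- numeric(max_bin + 1)
  rec <- function(i, bin, prob) {
    if (prob == 0) return()
    if (i > length(atom_opts)) {
      if (bin <= max_bin) out[bin + 1] <<- out[bin + 1] + prob
      return()
    }
    o <- atom_opts[[i]]
    for (j in seq_along(o$bins)) {
      rec(i + 1, bin + o$bins[j], prob * o$probs[j])
    }
  }
  rec(1, 0L, 1)
  out
}

# corrected-fraction long table builder for the quantifiability tests:
# one lipid over a design, with given control deuterated/M0 ratio and
# per-sample detected runs
make_quant_table <- function(design, control_ratio, run_by_sample,
                             max_n = 20) {
  rows <- list()
  for (i in seq_len(nrow(design))) {
    sid <- design$sample[i]
    grp <- design$group[i]
    frac <- numeric(max_n + 1)
    if (grp == "H2O_control") {
      frac[1] <- 1 / (1 + control_ratio)
      frac[2] <- control_ratio / (1 + control_ratio)
    } else {
      frac[1] <- 0.6
      frac[2:5] <- 0.1
    }
    det <- rep(FALSE, max_n + 1)
    det[1] <- TRUE
    len <- run_by_sample[[sid]] %||% 0
    if (len > 0) det[2:(1 + len)] <- TRUE
    rows[[sid]] <- tibble::tibble(
      sample = sid, lipid = "L1", n = 0:max_n, area = frac * 1e6,
      detected = det, fraction = frac)
  }
  dplyr::bind_rows(rows)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
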