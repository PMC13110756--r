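# Synthetic LC-MS and MSI data with known ground truth.
#
# The generator states the world the pipeline is tested against: 25%
# heavy-water enrichment in body water (the study design's nominal intake),
# binomial incorporation into accessible C-H positions with an efficiency
# factor, an unlabeled pre-existing pool, natural-abundance convolution at
# Orbitrap resolution, Gaussian chromatographic peaks, multiplicative area
# noise and ppm-scale centroid jitter.

#' Isotopologue distribution of a partially labeled pool
#'
#' Mixture of an unlabeled pool and a newly synthesised pool whose
#' deuterium count is binomial over the accessible hydrogens:
#' `(1 - f_new) * delta_0 + f_new * Binomial(n_h, p * efficiency)`,
#' truncated at `max_n` with the tail mass reported.
#'
#' @param p Body-water deuterium enrichment (default 0.25).
#' @param n_h Accessible hydrogen count.
#' @param f_new Fraction newly synthesised in `[0, 1]`.
#' @param efficiency Incorporation efficiency multiplying `p` (default 0.7).
#' @param max_n Grid upper index (default 20).
#' @return Probability vector over `M+0..M+max_n` with attribute `tail`.
#' @export
#' @examples
#' label_distribution(p = 0.5, n_h = 2, f_new = 1, efficiency = 1)
label_distribution <- function(p = 0.25, n_h, f_new, efficiency = 0.7,
                               max_n = 20L) {
  stopifnot(p >= 0, p <= 1, f_new >= 0, f_new <= 1,
            efficiency > 0, efficiency <= 1, n_h >= 0)
  pe <- p * efficiency
  lab <- stats::dbinom(0:max_n, n_h, pe)
  out <- f_new * lab
  out[1] <- out[1] + (1 - f_new)
  structure(out, tail = max(0, 1 - sum(out)))
}

#' Default synthetic lipid target set
#'
#' A small panel spanning the behaviour profiles: a constitutive
#' phosphatidylcholine, marker-class myelin sphingolipids and plasmalogen,
#' and a cuprizone-induced sphingomyelin. Accessible-hydrogen counts are
#' kept in the 10-40 range so the M+20 truncation is negligible.
#'
#' @return A [lipid_targets()] tibble with an added `profile` column.
#' @export
synth_targets <- function() {
  t <- lipid_targets(
    name = c("PC 34:1", "HexCer 18:1;O2/24:0;O", "PE P-18:0/18:1",
             "SM 42:1;O2"),
    adduct = c("[M+H]+", "[M+H]+", "[M-H]-", "[M+H]+"),
    rt = c(11.2, 13.1, 12.0, 14.3),
    n_h = c(30L, 34L, 32L, 36L))
  t$profile <- c("constitutive", "marker", "marker", "cpz_increased")
  t
}

# fraction newly synthesised per profile and group
.profile_fnew <- function(profile, group) {
  if (group == "H2O_control") return(0)
  switch(profile,
    constitutive = c(Ctrl = 0.40, Cpz = 0.40, Rem = 0.40)[[group]],
    marker = c(Ctrl = 0.10, Cpz = 0.00, Rem = 0.40)[[group]],
    cpz_increased = c(Ctrl = 0.20, Cpz = 0.50, Rem = 0.30)[[group]],
    stop("unknown profile '", profile, "'"))
}

#' Default synthetic cohort design
#'
#' Four samples per group for the three heavy-water arms and the
#' light-water control arm.
#'
#' @param n_per_group Samples per group (default 4).
#' @param n_control Samples in the light-water control arm (default 4).
#' @return A [study_design()] tibble.
#' @export
synth_design <- function(n_per_group = 4L, n_control = 4L) {
  groups <- c(rep("H2O_control", n_control),
              rep(LABELED_GROUPS, each = n_per_group))
  ids <- unlist(lapply(split(groups, groups)[unique(groups)], function(g) {
    paste0(g[1], "_", seq_along(g))
  }), use.names = FALSE)
  study_design(ids, groups)
}

#' Render one synthetic centroided LC-MS run
#'
#' Forward model: each target's labeling distribution is convolved with its
#' natural-abundance pattern through the correction matrix, scaled by a
#' total abundance, shaped into Gaussian chromatographic peaks at the
#' reference retention time, and emitted as centroid MS1 scans with
#' multiplicative area noise and ppm-scale m/z jitter.
#'
#' @param targets A [lipid_targets()] tibble.
#' @param f_new Named vector of per-lipid fractions newly synthesised.
#' @param sample_id Sample id (becomes the run id).
#' @param seed Integer seed; every random draw flows from it.
#' @param p,efficiency Labeling model (defaults 0.25, 0.7).
#' @param total_abundance Named vector of per-lipid total areas (default
#'   1e7 each).
#' @param area_cv Multiplicative per-isotopologue area CV (default 0.01).
#' @param min_intensity Detector noise floor in counts (default 10):
#'   centroids below it are not written, as in vendor peak picking.
#' @param mz_jitter_ppm Gaussian centroid m/z jitter (default 2 ppm).
#' @param peak_sigma Chromatographic Gaussian sigma in minutes (default 0.05).
#' @param scan_dt Scan spacing in minutes (default 0.01).
#' @param res [resolution_model()] used for the natural-abundance forward
#'   convolution.
#' @return List: `run` (a [centroid_run()]) and `truth` (tibble with the
#'   generated `area_true`, `f_new`, and the implied labeled molecule
#'   fraction `labeled_fraction` per lipid and isotopologue).
#' @export
render_lcms_run <- function(targets, f_new, sample_id, seed,
                            p = 0.25, efficiency = 0.7,
                            total_abundance = NULL, area_cv = 0.01,
                            min_intensity = 10,
                            mz_jitter_ppm = 2, peak_sigma = 0.05,
                            scan_dt = 0.01, res = resolution_model()) {
  stopifnot(all(targets$lipid %in% names(f_new)))
  if (is.null(total_abundance)) {
    total_abundance <- stats::setNames(rep(1e7, nrow(targets)),
                                       targets$lipid)
  }
  withr::local_seed(seed)
  rt_lo <- min(targets$rt) - 0.4
  rt_hi <- max(targets$rt) + 0.4
  rts <- seq(rt_lo, rt_hi, by = scan_dt)
  mz_list <- vector("list", length(rts))
  int_list <- vector("list", length(rts))
  for (i in seq_along(rts)) {
    mz_list[[i]] <- numeric(0)
    int_list[[i]] <- numeric(0)
  }
  truth <- list()
  for (t in seq_len(nrow(targets))) {
    tg <- targets[t, ]
    fn <- f_new[[tg$lipid]]
    dist <- label_distribution(p, tg$n_h, fn, efficiency, tg$max_n)
    cm <- correction_matrix(tg$formula[[1]], tg$mz0, res, tg$max_n)
    envelope <- as.numeric(unclass(cm) %*% as.numeric(dist))
    areas <- total_abundance[[tg$lipid]] * envelope
    noisy <- areas * exp(stats::rnorm(length(areas), 0, area_cv))
    noisy[areas == 0] <- 0
    grid <- isotopologue_mz(tg$formula[[1]], tg$adduct, 0:tg$max_n)
    height <- noisy / (peak_sigma * sqrt(2 * pi))
    sel_rt <- which(abs(rts - tg$rt) <= 4 * peak_sigma)
    for (k in seq_len(nrow(grid))) {
      if (height[k] <= 0) next
      y <- height[k] * exp(-(rts[sel_rt] - tg$rt)^2 / (2 * peak_sigma^2))
      mzk <- grid$mz[k] *
        (1 + stats::rnorm(length(sel_rt), 0, mz_jitter_ppm * 1e-6))
      keep <- y > height[k] * 1e-4 & y >= min_intensity
      for (j in which(keep)) {
        idx <- sel_rt[j]
        mz_list[[idx]] <- c(mz_list[[idx]], mzk[j])
        int_list[[idx]] <- c(int_list[[idx]], y[j])
      }
    }
    pe <- p * efficiency
    truth[[tg$lipid]] <- tibble::tibble(
      sample = sample_id, lipid = tg$lipid, n = grid$n,
      area_true = areas, f_new = fn,
      labeled_fraction = fn * (1 - (1 - pe)^tg$n_h))
  }
  for (i in seq_along(rts)) {
    o <- order(mz_list[[i]])
    mz_list[[i]] <- mz_list[[i]][o]
    int_list[[i]] <- int_list[[i]][o]
  }
  scans <- tibble::tibble(rt = rts, ms_level = 1L, mz = mz_list,
                          intensity = int_list)
  polarity <- if (all(targets$charge > 0)) "positive" else "mixed"
  list(run = centroid_run(scans, id = sample_id, polarity = polarity),
       truth = dplyr::bind_rows(truth))
}

#' Render the standard synthetic LC-MS cohort
#'
#' One run per sample of the design. Group-level fractions newly
#' synthesised follow each target's behaviour profile (`constitutive`,
#' `marker`, `cpz_increased`); per-animal biological variability is added
#' as a truncated Gaussian on `f_new` (light-water controls stay at 0).
#'
#' @param targets [synth_targets()]-style tibble with a `profile` column.
#' @param design A [study_design()] (default [synth_design()]).
#' @param seed Master seed; per-sample seeds are derived from it.
#' @param f_sd Between-animal SD of `f_new` (default 0.03).
#' @param ... Passed to [render_lcms_run()].
#' @return List: `runs` (named list of [centroid_run()]), `truth` (long
#'   tibble), `design`, `f_new` (per sample x lipid table).
#' @export
synth_lcms_cohort <- function(targets, design = synth_design(), seed = 1L,
                              f_sd = 0.03, ...) {
  stopifnot("profile" %in% names(targets))
  withr::local_seed(seed)
  sample_seeds <- sample.int(.Machine$integer.max, nrow(design))
  runs <- list()
  truths <- list()
  fnew_rows <- list()
  for (s in seq_len(nrow(design))) {
    sid <- design$sample[s]
    grp <- design$group[s]
    fn <- purrr::map_dbl(seq_len(nrow(targets)), function(t) {
      base <- .profile_fnew(targets$profile[t], grp)
      if (grp == "H2O_control" || base == 0) return(base)
      min(1, max(0, stats::rnorm(1, base, f_sd)))
    })
    names(fn) <- targets$lipid
    out <- render_lcms_run(targets, fn, sid, seed = sample_seeds[s], ...)
    runs[[sid]] <- out$run
    truths[[sid]] <- out$truth
    fnew_rows[[sid]] <- tibble::tibble(sample = sid, group = grp,
                                       lipid = targets$lipid, f_new = fn)
  }
  list(runs = runs, truth = dplyr::bind_rows(truths), design = design,
       f_new = dplyr::bind_rows(fnew_rows))
}

#' Default MSI phantom geometry
#'
#' A rectangular section with a corpus-callosum-like horizontal band (CC),
#' a striatum-like block (STR) beneath it, and background elsewhere.
#'
#' @param nx,ny Grid size in pixels (defaults 40 x 30).
#' @return List with `nx`, `ny` and the region `mask` tibble.
#' @export
msi_phantom_geometry <- function(nx = 40L, ny = 30L) {
  grid <- tidyr::expand_grid(x = seq_len(nx), y = seq_len(ny))
  cc_rows <- seq(round(ny * 0.55), round(ny * 0.70))
  str_rows <- seq(round(ny * 0.2), round(ny * 0.4))
  grid$region <- dplyr::case_when(
    grid$y %in% cc_rows ~ "CC",
    grid$y %in% str_rows & grid$x <= round(nx / 2) ~ "STR",
    TRUE ~ "background")
  list(nx = nx, ny = ny, mask = grid)
}

#' Render one synthetic MSI run
#'
#' Per-pixel centroid spectra containing the target's isotopologue peaks
#' (M+0 up to `max_iso`) and an internal-standard peak. Region-dependent
#' labeling (`f_new` per region) and abundance are forward-convolved with
#' natural abundance; a multiplicative per-pixel sensitivity field (smooth
#' gradient) scales every peak so that internal-standard normalisation is
#' exercised, and lognormal pixel noise is applied per peak.
#'
#' @param target One row of [lipid_targets()].
#' @param f_new_region Named vector: fraction newly synthesised per region
#'   (regions of the geometry mask).
#' @param abundance_region Named vector of per-region target abundance.
#' @param sample_id Sample id.
#' @param seed Integer seed.
#' @param geometry [msi_phantom_geometry()] output.
#' @param standard_mz m/z of the sprayed internal standard (default: the
#'   deuterated PC 33:1 standard ion).
#' @param standard_level Standard abundance before the sensitivity field.
#' @param pixel_cv Lognormal per-peak pixel noise CV (default 0.10).
#' @param sens_fun Optional `function(x, y)` giving the multiplicative
#'   per-pixel sensitivity; default is a smooth left-right gradient from
#'   0.4 to 1.6.
#' @param max_iso Highest isotopologue rendered (default 6).
#' @param p,efficiency Labeling model (defaults 0.25, 0.7).
#' @param res [resolution_model()] for the forward convolution.
#' @return List: `run` (an [msi_run()]), `mask`, `truth` (per region x
#'   isotopologue true normalised intensity, i.e. envelope x abundance /
#'   standard_level).
#' @export
render_msi_run <- function(target, f_new_region, abundance_region, sample_id,
                           seed, geometry = msi_phantom_geometry(),
                           standard_mz = NULL, standard_level = 1e4,
                           pixel_cv = 0.10, sens_fun = NULL, max_iso = 6L,
                           p = 0.25, efficiency = 0.7,
                           res = resolution_model(40000, 750, 0)) {
  stopifnot(nrow(target) == 1)
  withr::local_seed(seed)
  if (is.null(standard_mz)) {
    standard_mz <- mz_adduct(lipid_formula("PC 33:1"), "[M+H]+") +
      7 * tracer_mass_shift()
  }
  mask <- geometry$mask
  regions <- unique(mask$region)
  stopifnot(all(regions %in% names(f_new_region)),
            all(regions %in% names(abundance_region)))
  grid <- isotopologue_mz(target$formula[[1]], target$adduct, 0:max_iso)
  cm <- correction_matrix(target$formula[[1]], target$mz0, res, target$max_n)
  envelopes <- list()
  for (r in regions) {
    dist <- label_distribution(p, target$n_h, f_new_region[[r]], efficiency,
                               target$max_n)
    env <- as.numeric(unclass(cm) %*% as.numeric(dist))[seq_len(max_iso + 1)]
    envelopes[[r]] <- env * abundance_region[[r]]
  }
  # smooth multiplicative sensitivity field: left-right gradient
  if (is.null(sens_fun)) {
    sens_fun <- function(x, y) 0.4 + 1.2 * (x - 1) / max(1, geometry$nx - 1)
  }
  sens <- sens_fun(mask$x, mask$y)
  npx <- nrow(mask)
  mzs <- vector("list", npx)
  ints <- vector("list", npx)
  for (i in seq_len(npx)) {
    env <- envelopes[[mask$region[i]]]
    noise <- exp(stats::rnorm(max_iso + 2, 0, pixel_cv))
    peak_int <- c(env * noise[seq_len(max_iso + 1)],
                  standard_level * noise[max_iso + 2]) * sens[i]
    peak_mz <- c(grid$mz, standard_mz)
    keep <- peak_int > 0
    o <- order(peak_mz[keep])
    mzs[[i]] <- peak_mz[keep][o]
    ints[[i]] <- peak_int[keep][o]
  }
  pixels <- tibble::tibble(x = mask$x, y = mask$y, mz = mzs, intensity = ints)
  truth <- purrr::map_dfr(regions, function(r) {
    tibble::tibble(sample = sample_id, region = r, n = 0:max_iso,
                   normalised_true = envelopes[[r]] / standard_level,
                   f_new = f_new_region[[r]])
  })
  list(run = msi_run(pixels, id = sample_id,
                     polarity = target$polarity),
       mask = mask, truth = truth)
}

#' Render a synthetic MSI cohort
#'
#' One section per heavy-water sample. The corpus-callosum band carries the
#' group's labeling level; by default remyelination raises `f_new` in CC
#' five-fold over cuprizone so that the M+6 Rem-vs-Cpz region contrast is a
#' planted, recoverable fold change.
#'
#' @param target One row of [lipid_targets()].
#' @param design [study_design()] restricted to the heavy-water groups.
#' @param seed Master seed.
#' @param f_cc Named per-group `f_new` in the CC band
#'   (default `c(Ctrl = 0.25, Cpz = 0.1, Rem = 0.5)`).
#' @param f_bg `f_new` outside CC (default 0.15).
#' @param ... Passed to [render_msi_run()].
#' @return List: `runs`, `mask`, `truth` (including per-sample region
#'   ground truth), `design`.
#' @export
synth_msi_cohort <- function(target, design, seed = 1L,
                             f_cc = c(Ctrl = 0.25, Cpz = 0.10, Rem = 0.50),
                             f_bg = 0.15, ...) {
  design <- dplyr::filter(design, .data$group %in% LABELED_GROUPS)
  withr::local_seed(seed)
  sample_seeds <- sample.int(.Machine$integer.max, nrow(design))
  geometry <- msi_phantom_geometry()
  runs <- list()
  truths <- list()
  for (s in seq_len(nrow(design))) {
    sid <- design$sample[s]
    grp <- design$group[s]
    f_region <- c(CC = f_cc[[grp]], STR = f_bg, background = f_bg)
    a_region <- c(CC = 5e4, STR = 3e4, background = 2e4)
    out <- render_msi_run(target, f_region, a_region, sid,
                          seed = sample_seeds[s], geometry = geometry, ...)
    runs[[sid]] <- out$run
    truths[[sid]] <- dplyr::mutate(out$truth, group = grp)
  }
  list(runs = runs, mask = geometry$mask,
       truth = dplyr::bind_rows(truths), design = design)
}
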