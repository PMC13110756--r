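# Ion images, internal-standard normalisation, region statistics.

make_pixel_run <- function(df, pitch = 30) {
  msi_run(df, pitch = pitch, id = "s")
}

test_that("ion images window centroids by ppm and mark empty pixels", {
  run <- make_pixel_run(tibble::tibble(
    x = 1L, y = 1L, mz = list(c(700, 760.5851)),
    intensity = list(c(5, 42))))
  img <- extract_ion_image(run, 760.5851, ppm = 15)
  expect_equal(img$value, 42)
  # 20 ppm away with a 15 ppm window
  run2 <- make_pixel_run(tibble::tibble(
    x = 1L, y = 1L, mz = list(760.5851 * (1 + 20e-6)),
    intensity = list(42)))
  expect_equal(extract_ion_image(run2, 760.5851, 15)$value, 0)
  # missing pixels inside the bounding box are NA
  run3 <- make_pixel_run(tibble::tibble(
    x = c(1L, 3L), y = c(1L, 1L), mz = list(500, 500),
    intensity = list(1, 2)))
  img3 <- extract_ion_image(run3, 500, 15)
  expect_true(is.na(img3$value[img3$x == 2]))
})

test_that("ion images are additive over disjoint m/z windows", {
  withr::with_seed(9, {
    px <- tidyr::expand_grid(x = 1:5, y = 1:4) |>
      dplyr::mutate(
        mz = purrr::map(seq_len(20), ~ sort(stats::runif(30, 700, 710))),
        intensity = purrr::map(seq_len(20), ~ stats::runif(30)))
  })
  run <- make_pixel_run(px)
  lo <- extract_ion_image(run, 702, ppm = 500)
  hi <- extract_ion_image(run, 708, ppm = 500)
  # windows 702 +/- 0.351 and 708 +/- 0.354 are disjoint; a wide window
  # covering both equals the sum where both contribute
  both <- extract_ion_image(run, 705, ppm = 5000)  # 705 +/- 3.5
  covered <- both$value >= lo$value + hi$value - 1e-9
  expect_true(all(covered))
})

test_that("normalisation divides per pixel and propagates missingness", {
  grid <- tidyr::expand_grid(x = 1:3, y = 1:2)
  run <- make_pixel_run(dplyr::mutate(
    grid, mz = purrr::map(seq_len(6), ~ c(500, 600)),
    intensity = purrr::map(seq_len(6), ~ c(4, 2))))
  ion <- extract_ion_image(run, 500, 15)
  std <- extract_ion_image(run, 600, 15)
  norm <- normalize_to_standard(ion, std)
  expect_equal(norm$value, rep(2, 6))
  # zero standard becomes NA, not Inf
  std0 <- std
  std0$value[1] <- 0
  n0 <- normalize_to_standard(ion, std0)
  expect_true(is.na(n0$value[1]))
  expect_false(any(is.infinite(n0$value), na.rm = TRUE))
  expect_error(normalize_to_standard(ion, std[1:3, ]), "different pixel")
})

test_that("normalisation cancels any multiplicative sensitivity field", {
  withr::with_seed(14, {
    grid <- tidyr::expand_grid(x = 1:6, y = 1:5)
    field <- stats::runif(nrow(grid), 0.2, 3)
    ion_true <- stats::runif(nrow(grid), 1, 10)
    run <- make_pixel_run(dplyr::mutate(
      grid,
      mz = purrr::map(seq_len(30), ~ c(500, 600)),
      intensity = purrr::map(seq_len(30),
                             ~ c(ion_true[.x], 7) * field[.x])))
  })
  norm <- normalize_to_standard(extract_ion_image(run, 500, 15),
                                extract_ion_image(run, 600, 15))
  expect_equal(norm$value, ion_true / 7, tolerance = 1e-12)
})

test_that("region summaries average non-missing pixels per label", {
  grid <- tidyr::expand_grid(x = 1:4, y = 1:4)
  img <- structure(dplyr::mutate(grid, value = 3), class = c("ion_image",
                                                             "tbl_df",
                                                             "tbl", "data.frame"))
  mask <- dplyr::mutate(grid, region = ifelse(x <= 2, "CC", "background"))
  s <- region_summary(img, mask)
  expect_equal(s$mean, c(3, 3))
  expect_equal(sum(s$n_pixels), 16)
  # permutation invariance
  s2 <- region_summary(img[sample(16), ], mask)
  expect_equal(dplyr::arrange(s2, region), dplyr::arrange(s, region))
  # all-missing region
  img$value[mask$region == "CC"] <- NA
  s3 <- region_summary(img, mask)
  expect_true(is.na(s3$mean[s3$region == "CC"]))
  expect_equal(s3$n_pixels[s3$region == "CC"], 0)
})

test_that("phantom contrasts survive extraction and normalisation", {
  tg <- lipid_targets("PC 34:1", rt = 11.2, n_h = 30L)
  out <- render_msi_run(
    tg[1, ], f_new_region = c(CC = 0.5, STR = 0.1, background = 0.1),
    abundance_region = c(CC = 5e4, STR = 1e4, background = 1e4),
    sample_id = "s1", seed = 8, pixel_cv = 0.02)
  grid6 <- isotopologue_mz(tg$formula[[1]], "[M+H]+", 6)$mz
  std_mz <- mz_adduct(lipid_formula("PC 33:1"), "[M+H]+") +
    7 * tracer_mass_shift()
  img <- extract_ion_image(out$run, grid6, 15)
  std <- extract_ion_image(out$run, std_mz, 15)
  norm <- normalize_to_standard(img, std)
  s <- region_summary(norm, out$mask)
  truth <- out$truth[out$truth$n == 6, ]
  planted <- truth$normalised_true[truth$region == "CC"] /
    truth$normalised_true[truth$region == "background"]
  got <- s$mean[s$region == "CC"] / s$mean[s$region == "background"]
  expect_equal(got, planted, tolerance = 0.05)
  # raw (un-normalised) image is biased by the sensitivity gradient;
  # per-pixel agreement with truth holds after normalisation
  cc_true <- truth$normalised_true[truth$region == "CC"]
  cc_px <- norm$value[out$mask$region == "CC"]
  expect_equal(mean(cc_px, na.rm = TRUE), cc_true, tolerance = 0.02)
})

test_that("region ANOVA needs replicates and behaves at the null", {
  design <- study_design(c("a1", "a2", "b1", "b2", "c1", "c2"),
                         rep(c("Ctrl", "Cpz", "Rem"), each = 2))
  # every group sees the same {1, 2} values in each region: between-group
  # mean differences are exactly zero with non-zero within-group variance
  summaries <- tidyr::expand_grid(
    sample = design$sample, region = c("CC", "TH")) |>
    dplyr::mutate(mean = rep(c(1, 1, 2, 2), 3))
  st <- region_group_stats(summaries, design)
  expect_equal(st$anova$f, rep(0, 2), tolerance = 1e-12)
  expect_equal(st$anova$p, rep(1, 2), tolerance = 1e-12)
  expect_false(any(st$pairwise$significant))
  single <- summaries[summaries$sample %in% c("a1", "b1", "c1") &
                        summaries$region == "CC", ]
  expect_error(region_group_stats(single, design),
               "insufficient replicates")
})

test_that("imzML files round trip pixel spectra", {
  withr::with_seed(4, {
    px <- tidyr::expand_grid(x = 1:3, y = 1:2) |>
      dplyr::mutate(mz = purrr::map(1:6, ~ sort(stats::runif(5, 100, 900))),
                    intensity = purrr::map(1:6, ~ stats::runif(5, 0, 1e4)))
  })
  run <- msi_run(px, pitch = 30, id = "sec1")
  path <- withr::local_tempfile()
  write_imzml(run, path)
  back <- read_imzml(paste0(path, ".imzML"), id = "sec1")
  expect_equal(back$pixels$x, run$pixels$x)
  expect_equal(back$pixels$y, run$pixels$y)
  expect_equal(back$pixels$mz, run$pixels$mz, tolerance = 1e-12)
  expect_equal(back$pixels$intensity, run$pixels$intensity,
               tolerance = 1e-12)
  expect_equal(back$pitch, 30)
})
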