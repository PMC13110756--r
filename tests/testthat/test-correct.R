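# Natural-abundance correction: resolution partition, patterns, matrix,
# NNLS inversion.

test_that("resolution model reproduces the Orbitrap FWHM scaling", {
  res <- resolution_model(60000, 200)
  # R(760) = 60000 * sqrt(200/760); FWHM = mz / R
  expect_equal(fwhm(res, 760.5851),
               760.5851 / (60000 * sqrt(200 / 760.5851)),
               tolerance = 1e-12)
  expect_equal(round(fwhm(res, 760.5851), 4), 0.0247)
})

test_that("isotope partition classifies 13C and 18O as unresolved at m/z 760", {
  part <- isotope_partition(lipid_formula("PC 34:1"), 760.5851,
                            resolution_model())
  c13 <- part[part$element == "C" & part$mass_number == 13, ]
  expect_true(c13$unresolved)
  expect_equal(c13$grid_distance, 1.0062767 - 1.0033548, tolerance = 1e-4)
  o18 <- part[part$element == "O" & part$mass_number == 18, ]
  expect_true(o18$unresolved)
  expect_equal(o18$grid_distance, 2 * 1.0062767 - 2.0042450,
               tolerance = 1e-4)
})

test_that("an extreme resolving power resolves every non-tracer isotope", {
  part <- isotope_partition(lipid_formula("PC 34:1"), 760.5851,
                            resolution_model(1e7, 200))
  non_tracer <- part[!(part$element == "H" & part$mass_number == 2), ]
  expect_false(any(non_tracer$unresolved))
  # natural 2H sits exactly on the tracer grid (distance 0), so it can never
  # be resolved away: the matrix approaches the identity up to the natural
  # deuterium abundance of the hydrogens (~0.0094 for 82 H)
  m <- correction_matrix(lipid_formula("PC 34:1"), 760.5851,
                         resolution_model(1e7, 200), max_n = 10)
  expect_lt(max(abs(unclass(m) - diag(11))), 0.01)
  expect_true(all(diag(unclass(m)) > 0.99))
})

test_that("natural pattern matches the first-order per-atom ratio", {
  part <- isotope_partition(lipid_formula("PC 34:1"), 760.5851,
                            resolution_model())
  np <- natural_pattern(lipid_formula("PC 34:1"), part, 20)
  # independent first-order oracle: sum over atoms of a_heavy/a_light for
  # the bin-1 isotopes
  iso <- isotope_table()
  ab <- function(el, mn) iso$abundance[iso$element == el &
                                         iso$mass_number == mn]
  r1 <- 42 * ab("C", 13) / ab("C", 12) + 82 * ab("H", 2) / ab("H", 1) +
    1 * ab("N", 15) / ab("N", 14) + 8 * ab("O", 17) / ab("O", 16)
  expect_equal(np[2] / np[1], r1, tolerance = 1e-12)
  expect_equal(round(np[2] / np[1], 2), 0.47)
})

test_that("pattern trivia: no unresolved elements, independence of atoms", {
  part_none <- isotope_partition(chem_formula(P = 1, Na = 1), 100,
                                 resolution_model())
  np <- natural_pattern(chem_formula(P = 1, Na = 1), part_none, 5)
  expect_equal(as.numeric(np), c(1, 0, 0, 0, 0, 0))
  f <- chem_formula(C = 5, H = 8, O = 2)
  p1 <- natural_pattern(f, max_bin = 10)
  p2 <- natural_pattern(as_chem_formula(unclass(f) * 2), max_bin = 10)
  expect_equal(p2[1], p1[1]^2, tolerance = 1e-12)
})

test_that("correction matrix columns match the enumeration oracle", {
  # small formula: every isotopomer enumerated exactly. Evaluated at an m/z
  # where every heavy isotope is unresolved, so the full enumeration is the
  # exact expectation.
  f <- chem_formula(C = 3, H = 5, N = 1, O = 1)
  m <- correction_matrix(f, mz = 760, res = resolution_model(60000, 200),
                         max_n = 4)
  for (j in 0:4) {
    fj <- unclass(f)
    fj[["H"]] <- fj[["H"]] - j
    oracle <- enumeration_pattern(as_chem_formula(fj[fj > 0]),
                                  max_bin = 4 - j)
    expect_equal(unname(unclass(m)[(j + 1):5, j + 1]), oracle,
                 tolerance = 1e-10)
  }
  expect_true(all(unclass(m)[upper.tri(m)] == 0))
  expect_true(all(colSums(unclass(m)) <= 1 + 1e-12))
})

test_that("column 0 is the natural pattern of the unlabeled formula", {
  f <- lipid_formula("PC 34:1")
  res <- resolution_model()
  m <- correction_matrix(f, 760.5851, res, max_n = 8)
  np <- natural_pattern(f, isotope_partition(f, 760.5851, res), 8)
  expect_equal(unname(unclass(m)[, 1]), as.numeric(np), tolerance = 1e-12)
})

test_that("tracer purity redistributes tracer atoms binomially", {
  f <- chem_formula(C = 4, H = 8, O = 2)
  res <- resolution_model()
  m1 <- correction_matrix(f, 120, res, max_n = 3, purity = 1)
  m9 <- correction_matrix(f, 120, res, max_n = 3, purity = 0.9)
  expect_equal(unclass(m9)[, 1], unclass(m1)[, 1])  # j = 0 unaffected
  # j = 1: 0.9 x (1-tracer column) + 0.1 x (0-tracer column)
  expect_equal(unclass(m9)[, 2],
               0.9 * unclass(m1)[, 2] + 0.1 * unclass(m1)[, 1],
               tolerance = 1e-12)
})

test_that("matrix construction refuses more tracers than hydrogens", {
  expect_error(correction_matrix(chem_formula(C = 2, H = 3, O = 1), 60,
                                 max_n = 5),
               "only 3 hydrogens")
})

test_that("forward-convolve then NNLS-correct round trips exactly", {
  f <- lipid_formula("PC 34:1")
  m <- correction_matrix(f, 760.5851, max_n = 20)
  # natural pattern of the unlabeled species recovers a pure M+0 solution
  a0 <- unclass(m)[, 1]
  cd <- correct_series(a0, m)
  expect_lt(max(abs(cd$fraction - c(1, rep(0, 20)))), 1e-6)
  # random non-negative labeling distributions
  withr::with_seed(11, {
    for (rep in 1:20) {
      x <- stats::runif(21)
      x[sample(21, 12)] <- 0
      x <- x / sum(x)
      a <- as.numeric(unclass(m) %*% x)
      cd <- correct_series(a, m)
      expect_lt(max(abs(cd$fraction - x)), 1e-6)
      expect_true(all(cd$fraction >= 0))
    }
  })
})

test_that("fully resolved model makes correction the identity", {
  # up to the natural-2H term, which no resolving power can remove
  f <- lipid_formula("PC 34:1")
  m <- correction_matrix(f, 760.5851, resolution_model(1e7, 200),
                         max_n = 12)
  x <- c(0.2, 0.1, 0, 0.3, 0, 0, 0.4, rep(0, 6))
  cd <- correct_series(x * 5e6, m)
  expect_equal(cd$fraction, x, tolerance = 0.01)
  # forward-applied first, the round trip is exact regardless
  cd2 <- correct_series(as.numeric(unclass(m) %*% x), m)
  expect_equal(cd2$fraction, x, tolerance = 1e-9)
})

test_that("degenerate series raise distinct errors", {
  m <- correction_matrix(chem_formula(C = 4, H = 8, O = 2), 120, max_n = 3)
  expect_error(correct_series(rep(0, 4), m), "no signal")
  expect_error(correct_series(c(1, NA, 0, 0), m), "non-finite")
  expect_error(correct_series(c(1, 2), m), "does not match")
})

test_that("light-water control fixtures keep x0 at least 0.95", {
  tg <- synth_targets()
  out <- render_lcms_run(
    tg, stats::setNames(rep(0, nrow(tg)), tg$lipid), "ctrl", seed = 5)
  series <- extract_cohort(list(out$run), tg)
  corr <- correct_isotopologues(series, tg)
  x0 <- corr[corr$n == 0, ]
  expect_true(all(x0$fraction >= 0.95))
})

test_that("NNLS solves a textbook overdetermined problem", {
  a <- matrix(c(1, 0, 1, 0, 1, 1), nrow = 3)
  b <- c(2, -1, 1)
  fit <- nnls_solve(a, b)
  ls <- stats::coef(stats::lm.fit(a, b))
  if (all(ls >= 0)) {
    expect_equal(fit$x, unname(ls), tolerance = 1e-10)
  }
  # active constraint case: unconstrained solution is negative
  a2 <- diag(2)
  b2 <- c(-1, 3)
  fit2 <- nnls_solve(a2, b2)
  expect_equal(fit2$x, c(0, 3), tolerance = 1e-12)
  expect_equal(fit2$residual, 1, tolerance = 1e-12)
})
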