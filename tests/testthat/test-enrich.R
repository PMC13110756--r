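# Quantifiability criteria, percent deuteration, pools, statistics and
# classification.

test_that("quantifiability verdicts follow both criteria exactly", {
  design <- synth_design(n_per_group = 4, n_control = 2)
  runs4 <- stats::setNames(as.list(rep(0, nrow(design))), design$sample)
  # 3 of 4 Rem samples with runs of 4
  for (s in paste0("Rem_", 1:3)) runs4[[s]] <- 4
  tbl <- make_quant_table(design, control_ratio = 0.02, runs4)
  q <- quantifiability(tbl, design)
  expect_true(q$quantifiable)
  expect_true(q$quantifiable_in_Rem)
  expect_false(q$quantifiable_in_Ctrl)
  expect_equal(q$reasons, "")

  # control ratio above 5% fails criterion (i) with the named reason
  tbl2 <- make_quant_table(design, control_ratio = 0.08, runs4)
  q2 <- quantifiability(tbl2, design)
  expect_false(q2$quantifiable)
  expect_match(q2$reasons, "control-deuteration")

  # runs of only 3 everywhere fail criterion (ii)
  runs3 <- lapply(runs4, function(x) min(x, 3))
  runs3[paste0("Ctrl_", 1:4)] <- 3
  runs3[paste0("Cpz_", 1:4)] <- 3
  q3 <- quantifiability(make_quant_table(design, 0.02, runs3), design)
  expect_false(q3$quantifiable)
  expect_match(q3$reasons, "isotopologue-run")
})

test_that("criterion thresholds are sharp at the stated boundaries", {
  design <- synth_design(4, 2)
  runs <- stats::setNames(as.list(rep(0, nrow(design))), design$sample)
  for (s in paste0("Rem_", 1:3)) runs[[s]] <- 4
  # 0.049 vs 0.051 around the 5% ceiling
  expect_true(quantifiability(make_quant_table(design, 0.049, runs),
                              design)$quantifiable)
  expect_false(quantifiability(make_quant_table(design, 0.051, runs),
                               design)$quantifiable)
  # 2 of 4 vs 3 of 4 samples with the run
  runs2 <- runs
  runs2[["Rem_3"]] <- 0
  expect_false(quantifiability(make_quant_table(design, 0.02, runs2),
                               design)$quantifiable)
  expect_true(quantifiability(make_quant_table(design, 0.02, runs),
                              design)$quantifiable)
})

test_that("criterion (ii) is monotone in detected isotopologues", {
  design <- synth_design(4, 2)
  withr::with_seed(21, {
    for (rep in 1:10) {
      runs <- stats::setNames(
        as.list(sample(0:6, nrow(design), replace = TRUE)), design$sample)
      base <- quantifiability(make_quant_table(design, 0.02, runs), design)
      more <- lapply(runs, function(x) x + sample(0:3, 1))
      grown <- quantifiability(make_quant_table(design, 0.02, more), design)
      if (base$quantifiable) expect_true(grown$quantifiable)
    }
  })
})

test_that("missing controls raise an error", {
  design <- synth_design(4, 2)
  no_ctrl <- design[design$group != "H2O_control", ]
  tbl <- make_quant_table(no_ctrl, 0.02,
                          stats::setNames(as.list(rep(4, nrow(no_ctrl))),
                                          no_ctrl$sample))
  expect_error(quantifiability(tbl, no_ctrl), "no H2O_control")
})

test_that("percent deuteration is 100 x (1 - x0) and scale-invariant", {
  expect_equal(percent_deuteration(c(1, rep(0, 20))), 0)
  expect_equal(percent_deuteration(c(0.5, 0.5, rep(0, 19))), 50)
  # under the binomial model with many accessible hydrogens, labeled
  # molecules almost surely carry >= 1 deuterium, so the fraction-new is
  # recovered: 1 - (1-p)^n_h oracle
  p_eff <- 0.25 * 0.7
  x <- label_distribution(0.25, 30, 0.3, 0.7)
  expect_equal(percent_deuteration(as.numeric(x) / sum(x)),
               100 * 0.3 * (1 - (1 - p_eff)^30), tolerance = 1e-9)
  expect_equal(100 * 0.3 * (1 - (1 - p_eff)^30), 30, tolerance = 0.01)
})

test_that("pool sizes conserve the total and track x0", {
  df <- tibble::tibble(sample = "s", lipid = "L", n = 0:4,
                       area = c(60, 20, 10, 6, 4),
                       fraction = c(0.6, 0.2, 0.1, 0.06, 0.04))
  rec <- enrichment_records(df)
  expect_equal(rec$total, 100)
  expect_equal(rec$non_deuterated + rec$deuterated, rec$total)
  expect_equal(rec$deuterated, 40)
  # x0 = 1 means no deuterated pool
  df1 <- dplyr::mutate(df, fraction = c(1, 0, 0, 0, 0))
  expect_equal(enrichment_records(df1)$deuterated, 0)
  # response factors scale totals only
  rec_rf <- enrichment_records(df, response_factors = c(L = 2))
  expect_equal(rec_rf$total, 200)
  expect_equal(rec_rf$pct_deuteration, rec$pct_deuteration)
})

test_that("group tests pick ANOVA or t-test by quantifiable conditions", {
  design <- synth_design(4, 2)
  labeled <- design[design$group != "H2O_control", ]
  pct <- c(Ctrl = 10, Cpz = 12, Rem = 30)
  records <- labeled |>
    dplyr::mutate(lipid = "L1",
                  pct_deuteration = pct[group] + rep(c(-1, 0, 0.5, 0.5), 3))
  quant3 <- tibble::tibble(lipid = "L1", quantifiable = TRUE,
                           quantifiable_in_Ctrl = TRUE,
                           quantifiable_in_Cpz = TRUE,
                           quantifiable_in_Rem = TRUE)
  st3 <- group_tests(records, quant3)
  expect_equal(st3$table$test, "anova")
  expect_lt(st3$table$q, 0.01)
  expect_equal(nrow(st3$pairwise), 3)
  quant2 <- dplyr::mutate(quant3, quantifiable_in_Cpz = FALSE)
  st2 <- group_tests(records, quant2)
  expect_equal(st2$table$test, "t-test")
  quant1 <- dplyr::mutate(quant2, quantifiable_in_Ctrl = FALSE)
  st1 <- group_tests(records, quant1)
  expect_equal(st1$table$test, "untested")
  expect_true(is.na(st1$table$p))
})

test_that("identical groups give F = 0, p = 1; separation gives tiny p", {
  design <- synth_design(3, 0)
  vals <- rep(c(1, 2, 3), 3)  # same values in every group
  records <- design |>
    dplyr::mutate(lipid = "L", pct_deuteration = vals)
  quant <- tibble::tibble(lipid = "L", quantifiable = TRUE,
                          quantifiable_in_Ctrl = TRUE,
                          quantifiable_in_Cpz = TRUE,
                          quantifiable_in_Rem = TRUE)
  st <- group_tests(records, quant)
  expect_equal(st$table$statistic, 0)
  expect_equal(st$table$p, 1)
  # near-complete separation
  design4 <- synth_design(4, 0)
  sep <- design4[design4$group %in% c("Ctrl", "Rem"), ] |>
    dplyr::mutate(lipid = "L",
                  pct_deuteration = ifelse(group == "Ctrl", 0, 10) +
                    rep(c(-0.01, 0.01, 0, 0.005), 2))
  quant2 <- dplyr::mutate(quant, quantifiable_in_Cpz = FALSE)
  st2 <- group_tests(sep, quant2)
  expect_lt(st2$table$p, 1e-6)
})

test_that("tidy and glance expose the stats object", {
  design <- synth_design(3, 0)
  records <- design |>
    dplyr::mutate(lipid = "L", pct_deuteration = rep(c(1, 2, 3), 3))
  quant <- tibble::tibble(lipid = "L", quantifiable_in_Ctrl = TRUE,
                          quantifiable_in_Cpz = TRUE,
                          quantifiable_in_Rem = TRUE)
  st <- group_tests(records, quant)
  expect_s3_class(tidy(st), "tbl_df")
  expect_equal(glance(st)$n_anova, 1)
  expect_equal(nrow(tidy(st, pairwise = TRUE)), 3)
})

test_that("classification follows the marker definition", {
  design <- synth_design(4, 0)
  mk_records <- function(lipid, means, jit) {
    design |>
      dplyr::mutate(lipid = lipid,
                    pct_deuteration = means[group] + rep(jit, 3))
  }
  jit <- c(-0.8, 0.3, 0.5, 0)
  records <- dplyr::bind_rows(
    # deuterated through Cpz, rising: not a marker
    mk_records("always_on", c(Ctrl = 40, Cpz = 45, Rem = 50), jit),
    # absent in Cpz, strong Rem induction: marker
    mk_records("marker", c(Ctrl = 10, Cpz = 0.2, Rem = 30), jit),
    # flat: constitutive
    mk_records("flat", c(Ctrl = 20, Cpz = 20.2, Rem = 20.1), jit),
    # suppressed under Cpz but still well deuterated: decreased
    mk_records("down", c(Ctrl = 40, Cpz = 25, Rem = 41), jit))
  quant <- tibble::tibble(
    lipid = c("always_on", "marker", "flat", "down"),
    quantifiable = TRUE,
    quantifiable_in_Ctrl = TRUE,
    quantifiable_in_Cpz = c(TRUE, FALSE, TRUE, TRUE),
    quantifiable_in_Rem = TRUE)
  st <- group_tests(records, quant)
  cl <- classify_lipids(st, quant)
  got <- stats::setNames(cl$category, cl$lipid)
  expect_equal(got[["always_on"]], "increased-under-Cpz")
  expect_equal(got[["marker"]], "myelination-marker")
  expect_equal(got[["flat"]], "constitutive")
  expect_equal(got[["down"]], "decreased-under-Cpz")
})

test_that("display matrix zeroes non-quantifiable conditions", {
  design <- synth_design(2, 0)
  records <- design |>
    dplyr::mutate(lipid = "L", pct_deuteration = 25)
  quant <- tibble::tibble(lipid = "L", quantifiable_in_Ctrl = TRUE,
                          quantifiable_in_Cpz = FALSE,
                          quantifiable_in_Rem = TRUE)
  hm <- deuteration_matrix(records, quant)
  expect_equal(hm$Cpz_1, 0)
  expect_equal(hm$Ctrl_1, 25)
})
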