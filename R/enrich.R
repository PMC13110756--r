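# Quantifiability criteria, percent deuteration, pool sizes and the
# group-comparison statistics that define myelination-marker lipids.

LABELED_GROUPS <- c("Ctrl", "Cpz", "Rem")

#' Build a study design table
#'
#' @param sample Character vector of sample ids.
#' @param group Group label per sample: one of `"H2O_control"`, `"Ctrl"`,
#'   `"Cpz"`, `"Rem"`.
#' @return A tibble `sample`, `group`.
#' @export
study_design <- function(sample, group) {
  valid <- c("H2O_control", LABELED_GROUPS)
  if (!all(group %in% valid)) {
    stop("groups must be in {", paste(valid, collapse = ", "), "}")
  }
  if (anyDuplicated(sample)) stop("duplicate sample ids in design")
  tibble::tibble(sample = as.character(sample), group = group)
}

# longest run of TRUE in a logical vector
.longest_run <- function(flags) {
  if (length(flags) == 0 || !any(flags)) return(0L)
  r <- rle(flags)
  max(r$lengths[r$values])
}

#' Apply the quantifiability criteria
#'
#' A lipid shows quantifiable deuteration when (i) the summed abundance of
#' deuterated isotopologues relative to M+0, after isotope correction,
#' averaged over the unlabeled-water control samples, is below
#' `control_fraction` (default 5%); and (ii) at least `run_length` (default
#' 4) consecutive isotopologue peaks among M+1..M+max are detected in at
#' least `group_fraction` (default 75%, i.e. 3 of 4) of the samples of at
#' least one heavy-water group.
#'
#' @param data Long tibble with columns `sample`, `lipid`, `n`, `detected`
#'   and `fraction` (corrected fractions, needed for control samples).
#' @param design A [study_design()] tibble; must contain at least one
#'   `H2O_control` sample.
#' @param control_fraction Criterion (i) threshold (default 0.05).
#' @param run_length Criterion (ii) run length (default 4).
#' @param group_fraction Fraction of samples per group required to satisfy
#'   the run condition (default 0.75, rounded up).
#' @param per_sample_control Apply criterion (i) per control sample (every
#'   sample must pass) instead of to the control mean (default `FALSE`).
#' @return A tibble per lipid: `lipid`, `control_ratio`, `criterion_control`,
#'   `criterion_run`, `quantifiable`, `reasons`, plus logical columns
#'   `run_ok_<group>` and `quantifiable_in_<group>` per heavy-water group.
#' @export
quantifiability <- function(data, design, control_fraction = 0.05,
                            run_length = 4L, group_fraction = 0.75,
                            per_sample_control = FALSE) {
  need <- c("sample", "lipid", "n", "detected", "fraction")
  stopifnot(all(need %in% names(data)))
  controls <- design$sample[design$group == "H2O_control"]
  if (length(controls) == 0) stop("design has no H2O_control samples")
  df <- dplyr::left_join(data, design, by = "sample")

  # criterion (i): deuterated-to-M+0 ratio in the 1H2O-only controls
  ctrl_ratio <- df |>
    dplyr::filter(.data$group == "H2O_control") |>
    dplyr::group_by(.data$lipid, .data$sample) |>
    dplyr::summarise(
      ratio = sum(.data$fraction[.data$n >= 1]) / .data$fraction[.data$n == 0],
      .groups = "drop") |>
    dplyr::group_by(.data$lipid) |>
    dplyr::summarise(
      control_ratio = mean(.data$ratio),
      criterion_control = if (per_sample_control) {
        all(.data$ratio < control_fraction)
      } else mean(.data$ratio) < control_fraction,
      .groups = "drop")

  # criterion (ii): >= run_length consecutive detected isotopologues in
  # M+1..M+max, in >= ceiling(group_fraction * n) samples of a group
  runs <- df |>
    dplyr::filter(.data$group %in% LABELED_GROUPS, .data$n >= 1) |>
    dplyr::group_by(.data$lipid, .data$group, .data$sample) |>
    dplyr::summarise(
      run_ok = .longest_run(.data$detected[order(.data$n)]) >= run_length,
      .groups = "drop") |>
    dplyr::group_by(.data$lipid, .data$group) |>
    dplyr::summarise(
      group_ok = sum(.data$run_ok) >= ceiling(group_fraction * dplyr::n()),
      .groups = "drop")
  run_wide <- runs |>
    tidyr::pivot_wider(names_from = "group", values_from = "group_ok",
                       names_prefix = "run_ok_")
  for (g in LABELED_GROUPS) {
    col <- paste0("run_ok_", g)
    if (!col %in% names(run_wide)) run_wide[[col]] <- NA
  }

  out <- dplyr::full_join(ctrl_ratio, run_wide, by = "lipid")
  run_cols <- paste0("run_ok_", LABELED_GROUPS)
  out$criterion_run <- apply(out[run_cols], 1, function(v) any(v %in% TRUE))
  out$quantifiable <- out$criterion_control & out$criterion_run
  out$reasons <- purrr::pmap_chr(
    out[c("criterion_control", "criterion_run")],
    function(criterion_control, criterion_run) {
      r <- c(if (!isTRUE(criterion_control)) "control-deuteration",
             if (!isTRUE(criterion_run)) "isotopologue-run")
      if (length(r) == 0) "" else paste(r, collapse = ";")
    })
  # per-condition quantifiability (used to choose ANOVA vs t-test)
  for (g in LABELED_GROUPS) {
    out[[paste0("quantifiable_in_", g)]] <-
      out$criterion_control & (out[[paste0("run_ok_", g)]] %in% TRUE)
  }
  out
}

#' Percent deuteration of a corrected distribution
#'
#' The molar percentage of molecules carrying at least one deuterium:
#' `100 * (1 - x0)`.
#'
#' @param fraction Corrected fraction vector `x0..xN` (sums to 1), or a
#'   `corrected_distribution`.
#' @return Percentage in `[0, 100]`.
#' @export
#' @examples
#' percent_deuteration(c(0.5, 0.5, 0))  # 50
percent_deuteration <- function(fraction) {
  if (inherits(fraction, "corrected_distribution")) {
    fraction <- fraction$fraction
  }
  100 * (1 - fraction[1])
}

#' Atom-based molar enrichment (secondary measure)
#'
#' `100 * sum(i * x_i) / (N * sum(x_i))`: average deuterium content as a
#' percentage of the grid capacity. Provided alongside [percent_deuteration()]
#' for users who prefer an atom-weighted measure.
#'
#' @inheritParams percent_deuteration
#' @export
atom_enrichment <- function(fraction) {
  if (inherits(fraction, "corrected_distribution")) {
    fraction <- fraction$fraction
  }
  idx <- seq_along(fraction) - 1
  100 * sum(idx * fraction) / ((length(fraction) - 1) * sum(fraction))
}

#' Per-sample enrichment records
#'
#' Summarises the long corrected table into one record per sample and lipid:
#' percent deuteration and the sizes of the deuterated and non-deuterated
#' pools on the raw-signal scale (`total = sum of raw areas`, optionally
#' scaled by a per-class response factor; `non_deuterated = total * x0`;
#' `deuterated = total - non_deuterated`).
#'
#' @param data Long tibble with `sample`, `lipid`, `n`, `area`, `fraction`.
#' @param design Optional [study_design()] to append group labels.
#' @param response_factors Optional named vector of scalar response factors
#'   by lipid (multiplies `total`).
#' @return Tibble: `sample`, `lipid`, (`group`), `pct_deuteration`,
#'   `atom_pct`, `total`, `non_deuterated`, `deuterated`.
#' @export
enrichment_records <- function(data, design = NULL, response_factors = NULL) {
  stopifnot(all(c("sample", "lipid", "n", "area", "fraction") %in% names(data)))
  out <- data |>
    dplyr::group_by(.data$sample, .data$lipid) |>
    dplyr::arrange(.data$n, .by_group = TRUE) |>
    dplyr::summarise(
      pct_deuteration = percent_deuteration(.data$fraction),
      atom_pct = atom_enrichment(.data$fraction),
      total = sum(.data$area),
      .groups = "drop")
  if (!is.null(response_factors)) {
    rf <- unname(response_factors[out$lipid])
    rf[is.na(rf)] <- 1
    out$total <- out$total * rf
  }
  out <- out |>
    dplyr::mutate(
      non_deuterated = .data$total * (1 - .data$pct_deuteration / 100),
      deuterated = .data$total - .data$non_deuterated)
  if (!is.null(design)) {
    out <- dplyr::left_join(out, design, by = "sample") |>
      dplyr::relocate("group", .after = "lipid")
  }
  out
}

#' Group-comparison statistics per lipid
#'
#' For each lipid, compares percent deuteration across the heavy-water
#' groups in which it is quantifiable: one-way ANOVA with Tukey HSD pairwise
#' post tests when quantifiable in all three conditions, a two-sample t-test
#' when quantifiable in exactly two, untested otherwise. Raw p-values are
#' adjusted across all tested lipids by Benjamini-Hochberg.
#'
#' @param records Output of [enrichment_records()] including `group`.
#' @param quant Output of [quantifiability()].
#' @param response Column of `records` to test (default `pct_deuteration`).
#' @return An object of class `lipid_stats`: list with `table` (per lipid:
#'   `lipid`, `test`, `statistic`, `p`, `q`, group means/sd) and `pairwise`
#'   (Tukey or t-test contrasts with estimates and adjusted p).
#' @export
group_tests <- function(records, quant, response = "pct_deuteration") {
  stopifnot(response %in% names(records))
  recs <- dplyr::filter(records, .data$group %in% LABELED_GROUPS)
  lipids <- unique(recs$lipid)
  rows <- list()
  pair_rows <- list()
  for (lp in lipids) {
    qrow <- quant[quant$lipid == lp, ]
    in_groups <- if (nrow(qrow) == 1) {
      LABELED_GROUPS[purrr::map_lgl(
        LABELED_GROUPS,
        ~ isTRUE(qrow[[paste0("quantifiable_in_", .x)]]))]
    } else character(0)
    sub <- recs[recs$lipid == lp & recs$group %in% in_groups, ]
    means <- recs[recs$lipid == lp, ] |>
      dplyr::group_by(.data$group) |>
      dplyr::summarise(mean = mean(.data[[response]]),
                       sd = stats::sd(.data[[response]]), .groups = "drop")
    base <- tibble::tibble(
      lipid = lp,
      n_groups_quantifiable = length(in_groups),
      quantifiable_groups = paste(in_groups, collapse = ";"))
    for (g in LABELED_GROUPS) {
      base[[paste0("mean_", g)]] <- means$mean[match(g, means$group)]
      base[[paste0("sd_", g)]] <- means$sd[match(g, means$group)]
    }
    if (length(in_groups) >= 3) {
      sub$group <- factor(sub$group, levels = LABELED_GROUPS)
      fit <- stats::aov(stats::reformulate("group", response), data = sub)
      an <- summary(fit)[[1]]
      tk <- stats::TukeyHSD(fit)$group
      rows[[lp]] <- dplyr::mutate(base, test = "anova",
                                  statistic = an$`F value`[1],
                                  p = an$`Pr(>F)`[1])
      pair_rows[[lp]] <- tibble::tibble(
        lipid = lp, contrast = rownames(tk), estimate = tk[, "diff"],
        p_adj = tk[, "p adj"])
    } else if (length(in_groups) == 2) {
      v1 <- sub[[response]][sub$group == in_groups[1]]
      v2 <- sub[[response]][sub$group == in_groups[2]]
      tt <- stats::t.test(v2, v1, var.equal = TRUE)
      rows[[lp]] <- dplyr::mutate(base, test = "t-test",
                                  statistic = unname(tt$statistic),
                                  p = tt$p.value)
      pair_rows[[lp]] <- tibble::tibble(
        lipid = lp,
        contrast = paste0(in_groups[2], "-", in_groups[1]),
        estimate = mean(v2) - mean(v1), p_adj = tt$p.value)
    } else {
      rows[[lp]] <- dplyr::mutate(base, test = "untested",
                                  statistic = NA_real_, p = NA_real_)
    }
  }
  table <- dplyr::bind_rows(rows)
  table$q <- NA_real_
  tested <- !is.na(table$p)
  table$q[tested] <- stats::p.adjust(table$p[tested], method = "BH")
  pairwise <- dplyr::bind_rows(pair_rows)
  structure(list(table = table, pairwise = pairwise, response = response),
            class = "lipid_stats")
}

#' @export
print.lipid_stats <- function(x, ...) {
  cat("<lipid_stats> ", nrow(x$table), " lipids (",
      sum(x$table$test != "untested"), " tested) on '", x$response, "'\n",
      sep = "")
  invisible(x)
}

# q-value for one contrast of one lipid, combining the lipid-level FDR with
# the Tukey family adjustment: significant contrast requires lipid q < alpha
# and pairwise adjusted p < alpha
.contrast_significant <- function(stats, lipid, groups, alpha = 0.05) {
  tab <- stats$table[stats$table$lipid == lipid, ]
  if (nrow(tab) == 0 || is.na(tab$q) || tab$q >= alpha) return(list(ok = FALSE, est = NA_real_))
  pw <- stats$pairwise[stats$pairwise$lipid == lipid, ]
  hit <- pw[pw$contrast %in% c(paste0(groups[1], "-", groups[2]),
                               paste0(groups[2], "-", groups[1])), ]
  if (nrow(hit) == 0) return(list(ok = FALSE, est = NA_real_))
  est <- hit$estimate[1]
  if (hit$contrast[1] == paste0(groups[2], "-", groups[1])) est <- -est
  list(ok = hit$p_adj[1] < alpha, est = est)
}

#' Classify lipids into synthesis-behaviour categories
#'
#' Myelination-marker lipids show no deuteration during cuprizone
#' intoxication (non-quantifiable in Cpz, or mean Cpz percent deuteration
#' below the control-criterion floor) together with a statistically
#' significant increase in deuteration in remyelination relative to basal
#' conditions (Rem mean > Ctrl mean at `q < alpha`). Remaining lipids are
#' classified by the sign of the significant Cpz-vs-Ctrl contrast, or as
#' constitutive when nothing is significant.
#'
#' @param stats A [group_tests()] result.
#' @param quant A [quantifiability()] table.
#' @param alpha Significance level on FDR-adjusted q (default 0.05).
#' @param floor_pct Deuteration floor regarded as "absent" (default 5,
#'   mirroring the 5% control criterion).
#' @return The `stats$table` tibble with an added `category` column
#'   (`"myelination-marker"`, `"increased-under-Cpz"`,
#'   `"decreased-under-Cpz"`, `"constitutive"`).
#' @export
classify_lipids <- function(stats, quant, alpha = 0.05, floor_pct = 5) {
  stopifnot(inherits(stats, "lipid_stats"))
  tab <- stats$table
  category <- character(nrow(tab))
  for (i in seq_len(nrow(tab))) {
    lp <- tab$lipid[i]
    qrow <- quant[quant$lipid == lp, ]
    cpz_quant <- nrow(qrow) == 1 && isTRUE(qrow$quantifiable_in_Cpz)
    cpz_absent <- !cpz_quant ||
      (!is.na(tab$mean_Cpz[i]) && tab$mean_Cpz[i] < floor_pct)
    rem_up <- .contrast_significant(stats, lp, c("Rem", "Ctrl"), alpha)
    if (cpz_absent && rem_up$ok && !is.na(rem_up$est) && rem_up$est > 0) {
      category[i] <- "myelination-marker"
      next
    }
    cpz_ctrl <- .contrast_significant(stats, lp, c("Cpz", "Ctrl"), alpha)
    category[i] <- if (cpz_ctrl$ok && !is.na(cpz_ctrl$est)) {
      if (cpz_ctrl$est > 0) "increased-under-Cpz" else "decreased-under-Cpz"
    } else "constitutive"
  }
  dplyr::mutate(tab, category = category)
}

#' Heat-map-ready percent-deuteration matrix
#'
#' Lipids x samples matrix of percent deuteration; samples from conditions
#' in which a lipid is non-quantifiable are displayed as zero (matching the
#' convention of assigning zero for display while excluding those values
#' from statistics).
#'
#' @param records [enrichment_records()] output including `group`.
#' @param quant [quantifiability()] output.
#' @return A wide tibble: `lipid` column plus one column per sample.
#' @export
deuteration_matrix <- function(records, quant) {
  recs <- dplyr::filter(records, .data$group %in% LABELED_GROUPS)
  qlong <- quant |>
    dplyr::select("lipid", dplyr::starts_with("quantifiable_in_")) |>
    tidyr::pivot_longer(-"lipid", names_to = "group",
                        values_to = "quant_in",
                        names_prefix = "quantifiable_in_")
  recs |>
    dplyr::left_join(qlong, by = c("lipid", "group")) |>
    dplyr::mutate(display = ifelse(.data$quant_in %in% TRUE,
                                   .data$pct_deuteration, 0)) |>
    dplyr::select("lipid", "sample", "display") |>
    tidyr::pivot_wider(names_from = "sample", values_from = "display")
}
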