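# broom-style methods for the statistics objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a lipid_stats object
#'
#' @param x A [group_tests()] result.
#' @param pairwise Return the pairwise contrasts instead of the per-lipid
#'   omnibus table.
#' @param ... Ignored.
#' @return A tibble.
#' @export
tidy.lipid_stats <- function(x, pairwise = FALSE, ...) {
  if (pairwise) x$pairwise else x$table
}

#' @rdname tidy.lipid_stats
#' @export
glance.lipid_stats <- function(x, ...) {
  tab <- x$table
  tibble::tibble(
    n_lipids = nrow(tab),
    n_tested = sum(tab$test != "untested"),
    n_anova = sum(tab$test == "anova"),
    n_ttest = sum(tab$test == "t-test"),
    n_significant = sum(tab$q < 0.05, na.rm = TRUE))
}

#' Tidy MSI region statistics
#'
#' @param x A [region_group_stats()] result.
#' @param pairwise Return Tukey contrasts instead of the per-region ANOVAs.
#' @param ... Ignored.
#' @return A tibble.
#' @export
tidy.msi_stats <- function(x, pairwise = FALSE, ...) {
  if (pairwise) x$pairwise else x$anova
}

#' @rdname tidy.msi_stats
#' @export
glance.msi_stats <- function(x, ...) {
  tibble::tibble(
    n_tests = nrow(x$anova),
    n_significant_tukey = sum(x$pairwise$significant))
}
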