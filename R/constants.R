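# Physical constants and the packaged isotope table.

.lipidflux_env <- new.env(parent = emptyenv())

#' Packaged isotope masses and abundances
#'
#' Returns the isotope constants bundled with the package: monoisotopic masses
#' (atomic mass units) and natural abundances for the elements handled by the
#' formula machinery (C, H, N, O, P, S, Na, K). Deuterium (`H`, mass number 2)
#' doubles as the tracer isotope.
#'
#' @return A tibble with columns `element`, `mass_number`, `mass`, `abundance`.
#' @export
#' @examples
#' isotope_table()
isotope_table <- function() {
  tbl <- .lipidflux_env$isotopes
  if (is.null(tbl)) {
    path <- system.file("extdata", "isotopes.tsv", package = "lipidflux")
    tbl <- readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                           progress = FALSE)
    .lipidflux_env$isotopes <- tbl
  }
  tbl
}

# CODATA 2018 electron mass in u
ELECTRON_MASS <- 0.000548579909065

#' Mass difference between deuterium and protium
#'
#' The spacing of the deuterium isotopologue grid: mass(2H) - mass(1H),
#' approximately 1.0062767 u.
#'
#' @return A single number (atomic mass units).
#' @export
tracer_mass_shift <- function() {
  m <- isotope_table()
  m$mass[m$element == "H" & m$mass_number == 2] -
    m$mass[m$element == "H" & m$mass_number == 1]
}

# monoisotopic (lightest-isotope) mass lookup, named by element; D is 2H
.monoisotopic_masses <- function() {
  masses <- .lipidflux_env$mono_masses
  if (is.null(masses)) {
    tbl <- isotope_table()
    first <- tbl[!duplicated(tbl$element), ]
    masses <- stats::setNames(first$mass, first$element)
    masses[["D"]] <- tbl$mass[tbl$element == "H" & tbl$mass_number == 2]
    .lipidflux_env$mono_masses <- masses
  }
  masses
}
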