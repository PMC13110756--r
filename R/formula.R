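# Elemental formulas as named integer vectors over the supported element set.
# D (2H) is tracked separately from H.

FORMULA_ELEMENTS <- c("C", "H", "N", "O", "P", "S", "Na", "K", "D")

#' Build an elemental formula
#'
#' Formulas are named integer vectors over the supported elements
#' (C, H, N, O, P, S, Na, K, plus D for deuterium, tracked separately from H).
#'
#' @param ... Element counts, e.g. `chem_formula(C = 42, H = 82, N = 1, O = 8, P = 1)`.
#' @return A named integer vector of class `chem_formula`.
#' @export
#' @examples
#' chem_formula(C = 27, H = 46, O = 1)  # cholesterol
chem_formula <- function(...) {
  counts <- c(...)
  if (length(counts) == 0) stop("formula must contain at least one element")
  as_chem_formula(counts)
}

#' @rdname chem_formula
#' @param x A named numeric vector of element counts, or a formula string such
#'   as `"C42H82NO8P"`.
#' @export
as_chem_formula <- function(x) {
  if (is.character(x)) return(parse_formula_string(x))
  bad <- setdiff(names(x), FORMULA_ELEMENTS)
  if (length(bad) > 0) {
    stop("unsupported element(s): ", paste(bad, collapse = ", "))
  }
  if (any(x < 0) || any(x != round(x))) {
    stop("element counts must be non-negative integers")
  }
  out <- stats::setNames(integer(length(FORMULA_ELEMENTS)), FORMULA_ELEMENTS)
  out[names(x)] <- as.integer(round(x))
  if (sum(out) == 0) stop("formula must contain at least one atom")
  structure(out, class = "chem_formula")
}

#' @rdname chem_formula
#' @export
is_chem_formula <- function(x) inherits(x, "chem_formula")

# parse "C42H82NO8P" (Hill-ish order, no parentheses; D allowed)
parse_formula_string <- function(s) {
  s <- gsub("\\s", "", s)
  if (!grepl("^([A-Z][a-z]?[0-9]*)+$", s)) {
    stop("malformed formula string: '", s, "'")
  }
  m <- gregexpr("[A-Z][a-z]?[0-9]*", s)[[1]]
  toks <- regmatches(s, list(m))[[1]]
  counts <- integer(0)
  for (tok in toks) {
    el <- sub("[0-9]*$", "", tok)
    n <- sub("^[A-Za-z]+", "", tok)
    n <- if (nzchar(n)) as.integer(n) else 1L
    counts[el] <- (if (el %in% names(counts)) counts[[el]] else 0L) + n
  }
  as_chem_formula(counts)
}

#' @export
format.chem_formula <- function(x, ...) {
  parts <- character(0)
  for (el in FORMULA_ELEMENTS) {
    n <- x[[el]]
    if (n == 0) next
    parts <- c(parts, paste0(el, if (n > 1) n else ""))
  }
  paste(parts, collapse = "")
}

#' @export
print.chem_formula <- function(x, ...) {
  cat("<chem_formula> ", format(x), "\n", sep = "")
  invisible(x)
}

# arithmetic helpers (internal)
formula_add <- function(a, b) {
  out <- unclass(a)
  out[names(b)] <- out[names(b)] + unclass(b)
  as_chem_formula(out)
}

formula_subtract <- function(a, b) {
  out <- unclass(a)
  out[names(b)] <- out[names(b)] - unclass(b)
  if (any(out < 0)) stop("formula subtraction gives negative counts")
  as_chem_formula(out)
}

formula_scale <- function(a, k) as_chem_formula(unclass(a) * k)

#' Neutral monoisotopic mass of a formula
#'
#' Sum of lightest-isotope atomic masses (deuterium counted at the 2H mass).
#'
#' @param formula A `chem_formula`.
#' @return Mass in u.
#' @export
#' @examples
#' monoisotopic_mass(chem_formula(C = 27, H = 46, O = 1))  # 386.3549
monoisotopic_mass <- function(formula) {
  formula <- as_chem_formula(formula)
  masses <- .monoisotopic_masses()
  sum(unclass(formula) * masses[FORMULA_ELEMENTS])
}
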