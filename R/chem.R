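# Lipid shorthand parsing and m/z computation.
#
# Shorthand grammar: <CLASS> [P-|O-]<C>:<DB>[;O<k>] ( [/_] <C>:<DB>[;O<k>] )*
# either sum-composition ("PC 34:1") or sn-resolved ("PC 16:0_18:1",
# "PE P-18:0/18:1"); "cholesterol" as a literal. Only total composition and
# class determine the neutral formula, so sn-resolved and sum-composition
# forms of one species are identical by construction.

LIPID_CLASSES <- c("PC", "PE", "PE-P", "PE-O", "PS", "PI", "SM", "HexCer",
                   "SHexCer", "DG", "TG", "LPC", "LPE", "LPS", "Cer",
                   "cholesterol")

# classes whose ;O count has a sphingoid-base default of 2 when omitted
SPHINGOID_CLASSES <- c("SM", "Cer", "HexCer", "SHexCer")

# neutral formula from class + total carbons (c), double bonds (d) and
# ;O hydroxyl count (k). Closed forms follow the standard backbone +
# headgroup construction for each class.
.class_formula <- function(class, c, d, k) {
  f <- switch(class,
    "PC"    = c(C = c + 8, H = 2 * c - 2 * d + 16, N = 1, O = 8, P = 1),
    "LPC"   = c(C = c + 8, H = 2 * c - 2 * d + 18, N = 1, O = 7, P = 1),
    "PE"    = c(C = c + 5, H = 2 * c - 2 * d + 10, N = 1, O = 8, P = 1),
    "PE-O"  = c(C = c + 5, H = 2 * c - 2 * d + 12, N = 1, O = 7, P = 1),
    # plasmalogen: one double-bond equivalent fewer H than the alkyl ether
    "PE-P"  = c(C = c + 5, H = 2 * c - 2 * d + 10, N = 1, O = 7, P = 1),
    "LPE"   = c(C = c + 5, H = 2 * c - 2 * d + 12, N = 1, O = 7, P = 1),
    "PS"    = c(C = c + 6, H = 2 * c - 2 * d + 10, N = 1, O = 10, P = 1),
    "LPS"   = c(C = c + 6, H = 2 * c - 2 * d + 12, N = 1, O = 9, P = 1),
    "PI"    = c(C = c + 9, H = 2 * c - 2 * d + 15, O = 13, P = 1),
    "DG"    = c(C = c + 3, H = 2 * c - 2 * d + 4, O = 5),
    "TG"    = c(C = c + 3, H = 2 * c - 2 * d + 2, O = 6),
    "Cer"   = c(C = c, H = 2 * c - 2 * d + 1, N = 1, O = k + 1),
    "HexCer" = c(C = c + 6, H = 2 * c - 2 * d + 11, N = 1, O = k + 6),
    "SHexCer" = c(C = c + 6, H = 2 * c - 2 * d + 11, N = 1, O = k + 9, S = 1),
    "SM"    = c(C = c + 5, H = 2 * c - 2 * d + 13, N = 2, O = k + 4, P = 1),
    stop("unsupported lipid class: '", class, "'")
  )
  as_chem_formula(f[f > 0])
}

# hydrogens bound to O or N (exchange with water, so excluded from the
# accessible C-H count used as the default labeling-site number)
.class_exchangeable_h <- function(class, k) {
  switch(class,
    "PC" = 0, "TG" = 0,
    "LPC" = 1, "DG" = 1, "cholesterol" = 1,
    "PE" = 2, "PE-O" = 2, "PE-P" = 2,
    "LPE" = 3, "PS" = 3,
    "LPS" = 4, "PI" = 4,
    "Cer" = k + 1,
    "HexCer" = k + 4, "SHexCer" = k + 4,
    "SM" = k,
    stop("unsupported lipid class: '", class, "'")
  )
}

.parse_chain <- function(token, name) {
  m <- regmatches(token,
    regexec("^([PO]-)?([0-9]+):([0-9]+)(;O([0-9]*))?$", token))[[1]]
  if (length(m) == 0) {
    stop("malformed chain token '", token, "' in lipid name '", name, "'")
  }
  list(
    ether = if (nzchar(m[2])) sub("-", "", m[2]) else NA_character_,
    c = as.integer(m[3]),
    db = as.integer(m[4]),
    o = if (nzchar(m[5])) {
      if (nzchar(m[6])) as.integer(m[6]) else 1L
    } else NA_integer_
  )
}

#' Parse lipid shorthand names
#'
#' Converts shorthand such as `"PC 34:1"`, `"PC 16:0_18:1"`,
#' `"PE P-18:0/18:1"`, `"HexCer 18:1;O2/24:0;O"` or `"cholesterol"` into the
#' neutral elemental formula. Sixteen classes are supported (PC, PE, PE-P,
#' PE-O, PS, PI, SM, HexCer, SHexCer, DG, TG, LPC, LPE, LPS, Cer,
#' cholesterol). Sum-composition and sn-resolved forms of the same total
#' composition give identical formulas; `P-` (vinyl-ether plasmalogen) and
#' `O-` (alkyl ether) prefixes differ by one double-bond equivalent (2 H).
#' For sphingolipid classes an omitted `;O` count defaults to the usual
#' two-oxygen sphingoid base (`;O2`).
#'
#' @param name Character vector of shorthand names.
#' @return A tibble with one row per name: `name`, `class`, `total_c`,
#'   `total_db`, `total_o`, `n_chains`, `formula` (list of [chem_formula]),
#'   `formula_string`, and `n_h` (default accessible C-H hydrogen count).
#' @export
#' @examples
#' parse_lipid(c("PC 34:1", "HexCer 18:1;O2/24:0;O", "cholesterol"))
parse_lipid <- function(name) {
  purrr::map_dfr(name, .parse_lipid_one)
}

.parse_lipid_one <- function(name) {
  stopifnot(is.character(name), length(name) == 1)
  nm <- trimws(name)
  if (tolower(nm) == "cholesterol") {
    f <- chem_formula(C = 27, H = 46, O = 1)
    return(tibble::tibble(
      name = nm, class = "cholesterol", total_c = 27L, total_db = 5L,
      total_o = 1L, n_chains = 0L, formula = list(f),
      formula_string = format(f), n_h = 45L))
  }
  parts <- strsplit(nm, " ", fixed = TRUE)[[1]]
  if (length(parts) != 2) {
    stop("malformed lipid name '", nm,
         "': expected '<CLASS> <composition>'")
  }
  class <- parts[1]
  if (!class %in% setdiff(LIPID_CLASSES, c("PE-P", "PE-O", "cholesterol"))) {
    stop("unsupported lipid class: '", class, "'")
  }
  tokens <- strsplit(parts[2], "[/_]")[[1]]
  chains <- lapply(tokens, .parse_chain, name = nm)

  ethers <- purrr::map_chr(chains, "ether")
  if (any(!is.na(ethers))) {
    if (class != "PE") {
      stop("ether prefix only supported for PE (PE P-/PE O-) in '", nm, "'")
    }
    if (!is.na(ethers[1]) && all(is.na(ethers[-1]))) {
      class <- paste0("PE-", ethers[1])
    } else {
      stop("ether prefix must be on the first chain only in '", nm, "'")
    }
  }

  total_c <- sum(purrr::map_int(chains, "c"))
  total_db <- sum(purrr::map_int(chains, "db"))
  o_counts <- purrr::map_int(chains, "o")
  total_o <- sum(o_counts, na.rm = TRUE)
  if (class %in% SPHINGOID_CLASSES && all(is.na(o_counts))) {
    total_o <- 2L  # sphingoid-base default
  }
  f <- .class_formula(class, total_c, total_db, total_o)
  n_h <- unclass(f)[["H"]] - .class_exchangeable_h(class, total_o)
  tibble::tibble(
    name = nm, class = class, total_c = total_c, total_db = total_db,
    total_o = as.integer(total_o), n_chains = length(chains),
    formula = list(f), formula_string = format(f), n_h = as.integer(n_h))
}

#' Neutral formula of a single lipid name
#'
#' @param name One shorthand name.
#' @return A [chem_formula].
#' @export
#' @examples
#' lipid_formula("PC 34:1")
lipid_formula <- function(name) parse_lipid(name)$formula[[1]]

#' Supported adducts
#'
#' @return A tibble with `adduct`, `charge` and a `delta` list-column of
#'   element-count changes relative to the neutral molecule.
#' @export
adduct_table <- function() {
  tibble::tibble(
    adduct = c("[M+H]+", "[M+Na]+", "[M+K]+", "[M-H]-", "[M+H-H2O]+"),
    charge = c(1L, 1L, 1L, -1L, 1L),
    delta = list(c(H = 1), c(Na = 1), c(K = 1), c(H = -1), c(H = -1, O = -1))
  )
}

.adduct_lookup <- function(adduct) {
  # tolerate the typographic minus used in shorthand text
  adduct <- gsub("−", "-", adduct)
  tbl <- adduct_table()
  i <- match(adduct, tbl$adduct)
  if (is.na(i)) stop("unsupported adduct: '", adduct, "'")
  tbl[i, ]
}

#' m/z of an adduct ion
#'
#' Computes (neutral monoisotopic mass + adduct mass delta - charge x electron
#' mass) / |charge|. Only singly charged adducts are supported.
#'
#' @param formula A [chem_formula] or formula string; alternatively a lipid
#'   shorthand name via `name`.
#' @param adduct Adduct name, e.g. `"[M+H]+"`, `"[M-H]-"`.
#' @return m/z value.
#' @export
#' @examples
#' mz_adduct(lipid_formula("PC 34:1"), "[M+H]+")  # 760.5851
mz_adduct <- function(formula, adduct = "[M+H]+") {
  formula <- as_chem_formula(formula)
  ad <- .adduct_lookup(adduct)
  masses <- .monoisotopic_masses()
  delta <- ad$delta[[1]]
  m <- monoisotopic_mass(formula) + sum(delta * masses[names(delta)])
  (m - ad$charge * ELECTRON_MASS) / abs(ad$charge)
}

#' Ion m/z of a charged fragment formula
#'
#' For fragment formulas written as the intact ion (e.g. the phosphocholine
#' cation C5H15NO4P+), the m/z is the formula mass minus/plus the electron
#' mass according to polarity.
#'
#' @param formula A [chem_formula] or string.
#' @param charge +1 or -1.
#' @return m/z value.
#' @export
#' @examples
#' mz_ion("C5H15NO4P", charge = 1)   # 184.0733
#' mz_ion("C5H11NO5P", charge = -1)  # 196.0380
mz_ion <- function(formula, charge = 1L) {
  stopifnot(abs(charge) == 1)
  formula <- as_chem_formula(formula)
  monoisotopic_mass(formula) - sign(charge) * ELECTRON_MASS
}

#' Deuterium isotopologue m/z grid
#'
#' m/z of the M+n isotopologues on the deuterium spacing grid:
#' `mz(M+n) = mz(M+0) + n * (mass(2H) - mass(1H)) / |charge|`.
#'
#' @param formula Neutral formula (or string).
#' @param adduct Adduct name.
#' @param n Integer vector of isotopologue indices (default `0:20`).
#' @return A tibble with `n` and `mz`.
#' @export
#' @examples
#' isotopologue_mz(lipid_formula("PC 34:1"), "[M+H]+", n = 0:6)
isotopologue_mz <- function(formula, adduct = "[M+H]+", n = 0:20) {
  stopifnot(all(n >= 0), all(n == round(n)))
  ad <- .adduct_lookup(adduct)
  m0 <- mz_adduct(formula, adduct)
  tibble::tibble(n = as.integer(n),
                 mz = m0 + n * tracer_mass_shift() / abs(ad$charge))
}

#' Build a lipid target table
#'
#' A target couples a lipid species with its ionisation and chromatographic
#' context: adduct, polarity, reference retention time, isotopologue grid
#' length, and the accessible-hydrogen count used by the synthetic generator
#' and correction-matrix sizing.
#'
#' @param name Character vector of lipid shorthand names.
#' @param adduct Adduct per target (recycled).
#' @param rt Reference retention time in minutes (> 0), per target.
#' @param polarity `"positive"` or `"negative"`; defaults to the adduct's sign.
#' @param max_n Isotopologue grid upper index (default 20).
#' @param n_h Accessible hydrogens; `NA` takes the parsed default
#'   (non-exchangeable C-H count).
#' @return A tibble of class `lipid_targets`; one row per target, including
#'   `mz0` (monoisotopic ion m/z) and a `grid_exceeds_nh` flag when `max_n`
#'   extends past the chemically possible labeling.
#' @export
#' @examples
#' lipid_targets("PC 34:1", adduct = "[M+H]+", rt = 11.2)
lipid_targets <- function(name, adduct = "[M+H]+", rt, polarity = NULL,
                          max_n = 20L, n_h = NA_integer_) {
  parsed <- parse_lipid(name)
  k <- nrow(parsed)
  adduct <- rep_len(gsub("−", "-", adduct), k)
  rt <- rep_len(rt, k)
  max_n <- rep_len(as.integer(max_n), k)
  n_h <- rep_len(as.integer(n_h), k)
  if (any(rt <= 0)) stop("reference retention times must be > 0")
  if (any(max_n < 1)) stop("max_n must be >= 1")
  charge <- purrr::map_int(adduct, ~ .adduct_lookup(.x)$charge)
  if (is.null(polarity)) polarity <- ifelse(charge > 0, "positive", "negative")
  polarity <- rep_len(polarity, k)
  n_h <- ifelse(is.na(n_h), parsed$n_h, n_h)
  total_h <- purrr::map_int(parsed$formula, ~ unclass(.x)[["H"]])
  if (any(n_h > total_h)) stop("n_h exceeds total hydrogen count")
  out <- tibble::tibble(
    lipid = parsed$name, class = parsed$class, formula = parsed$formula,
    formula_string = parsed$formula_string, adduct = adduct,
    polarity = polarity, charge = charge, rt = rt, max_n = max_n,
    n_h = as.integer(n_h),
    mz0 = purrr::map2_dbl(parsed$formula, adduct, mz_adduct),
    grid_exceeds_nh = max_n > n_h)
  class(out) <- c("lipid_targets", class(out))
  out
}

#' Read a lipid target list from CSV
#'
#' Expected columns: `name`, `adduct`, `rt_min`; optional `polarity`,
#' `max_n`, `n_h`.
#'
#' @param path CSV file path.
#' @return A `lipid_targets` tibble (see [lipid_targets()]).
#' @export
read_targets <- function(path) {
  df <- readr::read_csv(path, comment = "#", show_col_types = FALSE,
                        progress = FALSE)
  need <- c("name", "adduct", "rt_min")
  missing <- setdiff(need, names(df))
  if (length(missing) > 0) {
    stop("target list lacks column(s): ", paste(missing, collapse = ", "))
  }
  lipid_targets(
    df$name, adduct = df$adduct, rt = df$rt_min,
    polarity = if ("polarity" %in% names(df)) df$polarity else NULL,
    max_n = if ("max_n" %in% names(df)) df$max_n else 20L,
    n_h = if ("n_h" %in% names(df)) df$n_h else NA_integer_)
}
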