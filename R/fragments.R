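# MS2 product-ion isotopologue assignment: localising deuterium between
# headgroup and acyl chains.

# fatty acyl building blocks
.fa_formula <- function(c, db, o = 0) {
  chem_formula(C = c, H = 2 * c - 2 * db, O = 2 + o)  # free acid RCOOH
}

.carboxylate_ion <- function(c, db) {
  chem_formula(C = c, H = 2 * c - 1 - 2 * db, O = 2)  # [RCOO]-
}

.chain_label <- function(ch) paste0(ch$c, ":", ch$db)

# sn-resolved chains of a lipid name (NULL for sum compositions)
.resolved_chains <- function(name) {
  nm <- trimws(name)
  if (tolower(nm) == "cholesterol") return(NULL)
  parts <- strsplit(nm, " ", fixed = TRUE)[[1]]
  if (length(parts) != 2) return(NULL)
  tokens <- strsplit(parts[2], "[/_]")[[1]]
  if (length(tokens) < 2) return(NULL)
  lapply(tokens, .parse_chain, name = nm)
}

.fragment_row <- function(name, formula, charge, d_max) {
  mz <- mz_ion(formula, charge)
  tibble::tibble(
    fragment = name, formula = list(formula),
    formula_string = format(formula),
    charge = as.integer(charge),
    polarity = ifelse(charge > 0, "positive", "negative"),
    d_max = as.integer(d_max),
    mz = mz)
}

#' Class-standard MS2 fragment catalog for a lipid target
#'
#' Emits the diagnostic product ions used for label localisation:
#' \itemize{
#'   \item PE and PE-P (negative mode): the phosphoethanolamine headgroup
#'     anion (m/z 140.0118), the dehydroglycerol phosphoethanolamine anion
#'     (m/z 196.0380, diagnostic for diacyl/plasmalogen vs alkyl-ether PE),
#'     per-chain fatty-acyl carboxylates for ester-linked chains, and the
#'     corresponding neutral losses of each ester chain.
#'   \item PC and SM (positive mode): the phosphocholine cation
#'     (m/z 184.0733).
#'   \item HexCer (positive mode): the hexose neutral loss
#'     `[M+H-C6H10O5]+` and the dehydrated long-chain-base cation.
#' }
#' Per-chain fragments require an sn-resolved name (`"PE P-18:0/18:1"`);
#' sum compositions emit headgroup fragments only. `d_max` defaults to the
#' hydrogen count of the fragment formula. Additional fragments can be
#' appended from a user CSV via [read_fragment_catalog()].
#'
#' @param target One row of a [lipid_targets()] tibble.
#' @return A tibble: `fragment`, `formula` (list), `formula_string`,
#'   `charge`, `polarity`, `d_max`, `mz`.
#' @export
#' @examples
#' t <- lipid_targets("PE P-18:0/18:1", adduct = "[M-H]-", rt = 12)
#' fragment_catalog(t[1, ])
fragment_catalog <- function(target) {
  stopifnot(nrow(target) == 1)
  class <- target$class
  neutral <- target$formula[[1]]
  chains <- .resolved_chains(target$lipid)
  rows <- list()
  if (class %in% c("PE", "PE-P", "PE-O")) {
    rows$pe_head <- .fragment_row(
      "phosphoethanolamine", chem_formula(C = 2, H = 7, N = 1, O = 4, P = 1),
      -1, 4)
    if (class != "PE-O") {
      # produced by diacyl PE and plasmalogens, not alkyl ethers
      rows$dg_pe <- .fragment_row(
        "dehydroglycerol phosphoethanolamine",
        chem_formula(C = 5, H = 11, N = 1, O = 5, P = 1), -1, 8)
    }
    if (!is.null(chains)) {
      ester <- chains[purrr::map_lgl(chains, ~ is.na(.x$ether))]
      for (ch in ester) {
        ion <- .carboxylate_ion(ch$c, ch$db)
        rows[[paste0("fa", .chain_label(ch))]] <- .fragment_row(
          paste0("FA ", .chain_label(ch), " carboxylate"), ion, -1,
          unclass(ion)[["H"]])
        # [M-H-RCOOH]-
        nl <- formula_subtract(formula_subtract(neutral,
                                                .fa_formula(ch$c, ch$db)),
                               chem_formula(H = 1))
        rows[[paste0("nl", .chain_label(ch))]] <- .fragment_row(
          paste0("neutral loss of FA ", .chain_label(ch)), nl, -1,
          unclass(nl)[["H"]])
      }
    }
  } else if (class %in% c("PC", "SM", "LPC")) {
    rows$pchol <- .fragment_row(
      "phosphocholine", chem_formula(C = 5, H = 15, N = 1, O = 4, P = 1),
      1, 13)
  } else if (class %in% c("HexCer", "SHexCer")) {
    # hexose loss: [M+H-C6H10O5]+
    hex_loss <- formula_add(
      formula_subtract(neutral, chem_formula(C = 6, H = 10, O = 5)),
      chem_formula(H = 1))
    rows$hex_loss <- .fragment_row("hexose neutral loss", hex_loss, 1,
                                   unclass(hex_loss)[["H"]] - 1)
    if (!is.null(chains)) {
      base <- chains[[1]]
      base_o <- if (is.na(base$o)) 2L else base$o
      # long-chain base (CcH(2c+3-2db)NO(base_o)) minus its hydroxyls as
      # water, protonated: e.g. the 264.2686 ion of an 18:1;O2 base
      bf <- c(C = base$c, H = 2 * base$c + 4 - 2 * base$db - 2 * base_o,
              N = 1)
      rows$lcb <- .fragment_row(
        paste0("sphingoid base ", .chain_label(base), " - 2H2O"),
        as_chem_formula(bf), 1, bf[["H"]])
    }
  }
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0) {
    stop("no class-standard fragments defined for class '", class, "'")
  }
  out
}

#' Read a user fragment catalog from CSV
#'
#' Columns: `fragment`, `formula` (ion formula string), `charge`; optional
#' `d_max` (defaults to the hydrogen count).
#'
#' @param path CSV path.
#' @return A catalog tibble compatible with [fragment_catalog()].
#' @export
read_fragment_catalog <- function(path) {
  df <- readr::read_csv(path, comment = "#", show_col_types = FALSE,
                        progress = FALSE)
  need <- c("fragment", "formula", "charge")
  missing <- setdiff(need, names(df))
  if (length(missing) > 0) {
    stop("fragment catalog lacks column(s): ", paste(missing, collapse = ", "))
  }
  purrr::pmap_dfr(df, function(fragment, formula, charge, d_max = NA, ...) {
    f <- as_chem_formula(formula)
    .fragment_row(fragment, f, charge,
                  if (is.na(d_max)) unclass(f)[["H"]] else d_max)
  })
}

#' Assign deuterium isotopologues to MS2 product ions
#'
#' For each catalog fragment and each deuterium count
#' `d = 0..min(d_max, k)`, matches spectrum centroids within `ppm` of the
#' theoretical m/z `fragment + d * 1.0062767 / |z|`, where `k` is the
#' precursor's deuterium count (the precursor isotopologue index that was
#' fragmented). At typical MS2 resolution a one-13C interpretation (shift
#' 1.0033548) is not mass-resolved from the one-2H interpretation; matched
#' peaks whose m/z is consistent with both within the MS2 peak width are
#' flagged `c13_ambiguous` rather than forced to one reading.
#'
#' @param spectrum Tibble with `mz`, `intensity` (one centroided MS2 scan);
#'   optional attribute/column `precursor_mz` checked against the M+k
#'   precursor.
#' @param target One row of [lipid_targets()].
#' @param k Precursor deuterium count (isotopologue index).
#' @param catalog A [fragment_catalog()] tibble (default: built from the
#'   target).
#' @param ppm Match tolerance (default 20 ppm, looser than MS1).
#' @param ms2_res A [resolution_model()] describing the MS2 scan (default
#'   15000 at m/z 200 with flat exponent 0).
#' @param precursor_check Verify the spectrum's `precursor_mz` (default TRUE
#'   when present).
#' @return Tibble of assignments: `fragment`, `d`, `mz_theoretical`,
#'   `mz_observed`, `ppm_error`, `intensity`, `c13_ambiguous`. Unmatched
#'   (fragment, d) pairs are omitted.
#' @export
assign_fragment_isotopologues <- function(spectrum, target, k,
                                          catalog = fragment_catalog(target),
                                          ppm = 20,
                                          ms2_res = resolution_model(15000, 200, 0),
                                          precursor_check = TRUE) {
  stopifnot(k >= 0, all(c("mz", "intensity") %in% names(spectrum)))
  if (!all(catalog$polarity == target$polarity)) {
    stop("fragment polarity does not match the target's ionisation mode")
  }
  pre_mz <- attr(spectrum, "precursor_mz")
  if (is.null(pre_mz) && "precursor_mz" %in% names(spectrum)) {
    pre_mz <- spectrum$precursor_mz[1]
  }
  if (precursor_check && !is.null(pre_mz) && !is.na(pre_mz)) {
    expect <- isotopologue_mz(target$formula[[1]], target$adduct, k)$mz
    if (abs(pre_mz - expect) > expect * 25e-6) {
      stop("spectrum precursor m/z ", round(pre_mz, 4),
           " is not the M+", k, " isotopologue (expected ",
           round(expect, 4), ")")
    }
  }
  shift2h <- tracer_mass_shift()
  shift13c <- {
    tbl <- isotope_table()
    tbl$mass[tbl$element == "C" & tbl$mass_number == 13] - 12
  }
  rows <- list()
  for (i in seq_len(nrow(catalog))) {
    frag <- catalog[i, ]
    for (d in 0:min(frag$d_max, k)) {
      mz_th <- frag$mz + d * shift2h / abs(frag$charge)
      sel <- which(abs(spectrum$mz - mz_th) <= mz_th * ppm * 1e-6)
      if (length(sel) == 0) next
      j <- sel[which.max(spectrum$intensity[sel])]
      obs <- spectrum$mz[j]
      # would a (d-1) x 2H + 1 x 13C reading also fit within the peak width?
      amb <- FALSE
      if (d >= 1) {
        alt <- frag$mz + ((d - 1) * shift2h + shift13c) / abs(frag$charge)
        amb <- abs(obs - alt) < fwhm(ms2_res, mz_th)
      }
      rows[[length(rows) + 1]] <- tibble::tibble(
        fragment = frag$fragment, d = d, mz_theoretical = mz_th,
        mz_observed = obs,
        ppm_error = (obs - mz_th) / mz_th * 1e6,
        intensity = spectrum$intensity[j], c13_ambiguous = amb)
    }
  }
  if (length(rows) == 0) {
    return(tibble::tibble(fragment = character(), d = integer(),
                          mz_theoretical = double(), mz_observed = double(),
                          ppm_error = double(), intensity = double(),
                          c13_ambiguous = logical()))
  }
  dplyr::bind_rows(rows)
}
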