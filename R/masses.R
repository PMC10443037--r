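#' Monoisotopic atomic mass table
#'
#' Fixed table of IUPAC monoisotopic atomic masses (Da) embedded in the
#' package, including the heavy-isotope labels used by isotopologue infusion
#' standards (`D`/`2H`, `13C`, `15N`, `18O`). The table is versioned and never
#' fetched at runtime so that every mass computed by the package is
#' reproducible.
#'
#' @return Named numeric vector of monoisotopic masses in Da, with a
#'   `version` attribute identifying the table revision.
#' @examples
#' atomic_mass_table()[["C"]]  # 12 exactly, by definition of the Da
#' @export
atomic_mass_table <- function() {
  masses <- c(
    H  = 1.00782503207,
    D  = 2.01410177785,   # deuterium label, alias of 2H
    `2H` = 2.01410177785,
    C  = 12.0,
    `13C` = 13.00335483507,
    N  = 14.0030740048,
    `15N` = 15.0001088982,
    O  = 15.9949146196,
    `18O` = 17.9991610,
    P  = 30.97376163,
    S  = 31.97207100,
    F  = 18.99840322,
    Na = 22.9897692809,
    K  = 38.96370668,
    Cl = 34.96885268,
    Br = 78.9183371,
    I  = 126.904473,
    Si = 27.9769265325
  )
  attr(masses, "version") <- "IUPAC-2013/pciqc-1"
  masses
}

#' Physical constants used in m/z arithmetic
#'
#' @format `pci_electron_mass` is the electron rest mass in Da (CODATA);
#'   `pci_lockmass_mz` is the leucine-enkephalin lock-mass reference value
#'   556.2771, stored verbatim in the hydrogen-atom convention (neutral mass
#'   plus one H atom, no electron correction) as printed by TOF instrument
#'   software, rather than recomputed, to avoid a ~1 ppm systematic offset
#'   against the instrument convention.
#' @name pci-constants
NULL

#' @rdname pci-constants
#' @export
pci_electron_mass <- 0.00054857990907

#' @rdname pci-constants
#' @export
pci_lockmass_mz <- 556.2771

#' Parse an elemental formula string
#'
#' Accepts Hill-style formulas such as `"C8H10N4O2"`. Heavy-isotope labels are
#' written either with the `D` symbol (deuterium) or in bracket notation,
#' e.g. `"C8[13C]6H11Cl2NO2"` for a 13C6 label. Counts default to 1.
#'
#' @param formula Character scalar.
#' @return Named integer vector of element counts (class `pci_formula`).
#' @examples
#' parse_formula("H2O")
#' parse_formula("C8[13C]6H11Cl2NO2")  # diclofenac-13C6
#' @export
parse_formula <- function(formula) {
  stopifnot(is.character(formula), length(formula) == 1L, nzchar(formula))
  pat <- "\\[([0-9]+[A-Z][a-z]?)\\]([0-9]*)|([A-Z][a-z]?)([0-9]*)"
  m <- gregexpr(pat, formula, perl = TRUE)[[1]]
  toks <- regmatches(formula, list(m))[[1]]
  if (sum(attr(m, "match.length")) != nchar(formula)) {
    stop("cannot parse formula: '", formula, "'")
  }
  counts <- integer(0)
  for (tok in toks) {
    if (startsWith(tok, "[")) {
      sym <- sub("^\\[([^]]+)\\].*$", "\\1", tok)
      n <- sub("^\\[[^]]+\\]", "", tok)
    } else {
      sym <- sub("^([A-Z][a-z]?).*$", "\\1", tok)
      n <- sub("^[A-Z][a-z]?", "", tok)
    }
    n <- if (nzchar(n)) as.integer(n) else 1L
    if (n < 1L) stop("element count must be >= 1 in '", formula, "'")
    counts[sym] <- (if (sym %in% names(counts)) counts[[sym]] else 0L) + n
  }
  structure(counts, class = "pci_formula")
}

#' Monoisotopic mass of an elemental formula
#'
#' Exact sum of count times monoisotopic atomic mass over the embedded table
#' ([atomic_mass_table()]).
#'
#' @param formula Character formula string or a named count vector as
#'   returned by [parse_formula()].
#' @return Mass in Da.
#' @examples
#' monoisotopic_mass("H2O")           # 18.010565
#' monoisotopic_mass("C28H37N5O7")    # leucine enkephalin, 555.2693
#' @export
monoisotopic_mass <- function(formula) {
  if (is.character(formula)) formula <- parse_formula(formula)
  counts <- unclass(formula)
  stopifnot(length(counts) >= 1L, !is.null(names(counts)))
  tab <- atomic_mass_table()
  unknown <- setdiff(names(counts), names(tab))
  if (length(unknown)) {
    stop("unknown element symbol(s): ", paste(unknown, collapse = ", "))
  }
  sum(as.numeric(counts) * tab[names(counts)])
}

#' Adduct specification
#'
#' Describes how a neutral molecule is observed as an ion: the adducting
#' species added to the neutral mass, the charge, and whether the electron
#' mass is subtracted per positive charge. Instrument software often reports
#' singly protonated ions in the hydrogen-atom convention
#' (`electron_correction = FALSE`); physically exact m/z uses
#' `electron_correction = TRUE`. The two differ by 0.00055 Da for singly
#' charged ions.
#'
#' @param name Label such as `"[M+H]+"`.
#' @param added_formula Formula string of the added species (`""` for none).
#' @param charge Positive integer charge.
#' @param electron_correction Subtract one electron mass per charge?
#' @return An object of class `pci_adduct`.
#' @examples
#' adduct_spec("[M+Na]+", "Na")
#' @export
adduct_spec <- function(name, added_formula = "H", charge = 1L,
                        electron_correction = TRUE) {
  charge <- as.integer(charge)
  if (is.na(charge) || charge < 1L) stop("adduct charge must be >= 1")
  structure(
    list(name = name, added_formula = added_formula, charge = charge,
         electron_correction = isTRUE(electron_correction)),
    class = "pci_adduct"
  )
}

#' m/z of a neutral mass under an adduct
#'
#' `(M + mass(added) - e * z * m_e) / z` where `e` is 1 when the electron
#' correction is applied and 0 otherwise.
#'
#' @param neutral_mass Neutral monoisotopic mass in Da (> 0).
#' @param adduct A [adduct_spec()] object.
#' @return m/z value.
#' @examples
#' M <- monoisotopic_mass("C28H37N5O7")
#' adduct_mz(M, adduct_spec("[M+H]+", "H", 1, electron_correction = FALSE))
#' # 556.2771 -- the leucine-enkephalin lock mass in the instrument convention
#' @export
adduct_mz <- function(neutral_mass, adduct) {
  stopifnot(inherits(adduct, "pci_adduct"), neutral_mass > 0)
  add <- if (nzchar(adduct$added_formula)) {
    monoisotopic_mass(adduct$added_formula)
  } else 0
  e <- if (adduct$electron_correction) pci_electron_mass else 0
  (neutral_mass + add - e * adduct$charge) / adduct$charge
}

#' Symmetric ppm tolerance window around an m/z
#'
#' @param mz Target m/z (> 0).
#' @param tol Tolerance in ppm (>= 0).
#' @return Numeric length-2 vector `c(low, high)`; `low` is clamped at 0 for
#'   degenerate tolerances of 1e6 ppm or more.
#' @examples
#' ppm_window(500, 10)  # c(499.995, 500.005)
#' @export
ppm_window <- function(mz, tol) {
  stopifnot(mz > 0, tol >= 0)
  c(max(0, mz * (1 - tol * 1e-6)), mz * (1 + tol * 1e-6))
}
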