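#' Read a postcolumn-infusion standards panel
#'
#' A panel lists the infused standards: name, elemental formula *or* an
#' explicit m/z, the adducts to monitor, and the infusion-solution
#' concentration in mg/L. Panels are YAML files (see
#' `system.file("extdata", "standards.yaml", package = "pciqc")` for the
#' shipped default) or TSV files with columns `name`, `formula` (or `mz`),
#' `adducts` (comma-separated), `infusion_conc_mg_per_L`.
#'
#' Adduct names recognised: `[M+H]+`, `[M+Na]+`, `[M+K]+`, `[M+NH4]+`, or
#' `[M]+` (pass-through). User panels default to the electron-corrected
#' (physically exact) m/z convention.
#'
#' @param path Path to a YAML or TSV panel file.
#' @param electron_correction Convention for computed adduct m/z.
#' @return A data frame of class `pci_panel`: one row per (standard, adduct)
#'   with columns `name`, `formula`, `adduct`, `mz`, `conc_mg_per_L`,
#'   `primary` (logical, TRUE for the first adduct of each standard).
#' @export
read_panel <- function(path, electron_correction = TRUE) {
  stopifnot(file.exists(path))
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    doc <- yaml::read_yaml(path)
    rows <- lapply(doc$standards, function(s) {
      data.frame(
        name = s$name,
        formula = if (is.null(s$formula)) NA_character_ else s$formula,
        mz_explicit = if (is.null(s$mz)) NA_real_ else as.numeric(s$mz),
        adduct = as.character(unlist(s$adducts)),
        conc_mg_per_L = as.numeric(s$infusion_conc_mg_per_L),
        stringsAsFactors = FALSE
      )
    })
    tab <- do.call(rbind, rows)
  } else {
    raw <- utils::read.delim(path, stringsAsFactors = FALSE)
    if (!"adducts" %in% names(raw)) raw$adducts <- "[M+H]+"
    if (!"formula" %in% names(raw)) raw$formula <- NA_character_
    if (!"mz" %in% names(raw)) raw$mz <- NA_real_
    rows <- lapply(seq_len(nrow(raw)), function(i) {
      data.frame(
        name = raw$name[i], formula = raw$formula[i],
        mz_explicit = as.numeric(raw$mz[i]),
        adduct = trimws(strsplit(raw$adducts[i], ",")[[1]]),
        conc_mg_per_L = as.numeric(raw$infusion_conc_mg_per_L[i]),
        stringsAsFactors = FALSE
      )
    })
    tab <- do.call(rbind, rows)
  }
  build_panel(tab, electron_correction)
}

known_adducts <- function(electron_correction = TRUE) {
  list(
    "[M+H]+"   = adduct_spec("[M+H]+", "H", 1L, electron_correction),
    "[M+Na]+"  = adduct_spec("[M+Na]+", "Na", 1L, electron_correction),
    "[M+K]+"   = adduct_spec("[M+K]+", "K", 1L, electron_correction),
    "[M+NH4]+" = adduct_spec("[M+NH4]+", "NH4", 1L, electron_correction),
    "[M]+"     = adduct_spec("[M]+", "", 1L, electron_correction)
  )
}

build_panel <- function(tab, electron_correction = TRUE) {
  adds <- known_adducts(electron_correction)
  bad <- setdiff(unique(tab$adduct), names(adds))
  if (length(bad)) stop("unknown adduct name(s): ", paste(bad, collapse = ", "))
  mz <- numeric(nrow(tab))
  for (i in seq_len(nrow(tab))) {
    if (!is.na(tab$mz_explicit[i])) {
      mz[i] <- tab$mz_explicit[i]
    } else if (!is.na(tab$formula[i])) {
      mz[i] <- adduct_mz(monoisotopic_mass(tab$formula[i]), adds[[tab$adduct[i]]])
    } else {
      stop("standard '", tab$name[i], "' has neither formula nor explicit m/z")
    }
  }
  out <- data.frame(
    name = tab$name, formula = tab$formula, adduct = tab$adduct, mz = mz,
    conc_mg_per_L = tab$conc_mg_per_L,
    primary = !duplicated(tab$name),
    stringsAsFactors = FALSE
  )
  if (anyDuplicated(paste(out$name, out$adduct))) {
    stop("duplicate (standard, adduct) entries in panel")
  }
  class(out) <- c("pci_panel", "data.frame")
  out
}

#' Default standards panel
#'
#' The eight-standard isotopologue panel shipped with the package
#' (metformin-d6, atenolol-d7, acetaminophen-d4, caffeine-d3, nifedipine-d6,
#' diclofenac-13C6, lacidipine-13C8, simvastatin-d6) with the documented
#' infusion concentrations.
#'
#' @inheritParams read_panel
#' @return A `pci_panel` data frame.
#' @export
default_panel <- function(electron_correction = TRUE) {
  read_panel(system.file("extdata", "standards.yaml", package = "pciqc"),
             electron_correction = electron_correction)
}

#' Primary monitored ions of a panel
#'
#' One row per standard: its first-listed adduct, used as the default XIC
#' target for matrix-effect profiles.
#'
#' @param panel A `pci_panel`.
#' @return Subset of the panel with `primary == TRUE`.
#' @export
panel_targets <- function(panel) {
  stopifnot(inherits(panel, "pci_panel"))
  panel[panel$primary, , drop = FALSE]
}
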