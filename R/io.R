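#' Channel assignment rules for reading mzML
#'
#' Vendor-neutral mzML has no standard tag for MSe-style alternating
#' collision-energy functions, so scans are assigned to channels by an
#' explicit, auditable rule table: first by regex match against the scan
#' filter string, then by a collision-energy threshold (<= `ce_low_max` eV is
#' low energy, anything higher is the fragmenting channel).
#'
#' @param low_pattern,high_pattern,lock_pattern Regexes tested against the
#'   scan filter string.
#' @param ce_low_max Collision-energy threshold in eV for the fallback rule.
#' @return A named list of rules.
#' @export
default_channel_rules <- function(low_pattern = "channel=low_energy",
                                  high_pattern = "channel=high_energy",
                                  lock_pattern = "channel=lockmass",
                                  ce_low_max = 4) {
  list(low_pattern = low_pattern, high_pattern = high_pattern,
       lock_pattern = lock_pattern, ce_low_max = ce_low_max)
}

assign_channel <- function(filter_string, collision_energy, rules) {
  fs <- if (is.na(filter_string)) "" else filter_string
  if (nzchar(fs)) {
    if (grepl(rules$lock_pattern, fs)) return("lockmass")
    if (grepl(rules$low_pattern, fs)) return("low_energy")
    if (grepl(rules$high_pattern, fs)) return("high_energy")
  }
  if (!is.na(collision_energy)) {
    return(if (collision_energy <= rules$ce_low_max) "low_energy" else "high_energy")
  }
  NA_character_
}

# local-maximum centroiding with 3-point parabolic apex interpolation,
# for profile-mode input
centroid_profile <- function(mz, intensity) {
  n <- length(mz)
  if (n < 3L) return(list(mz = mz, intensity = intensity))
  i <- which(intensity[2:(n - 1)] > intensity[1:(n - 2)] &
               intensity[2:(n - 1)] >= intensity[3:n]) + 1L
  if (!length(i)) return(list(mz = numeric(0), intensity = numeric(0)))
  y1 <- log(pmax(intensity[i - 1L], 1e-12))
  y2 <- log(pmax(intensity[i], 1e-12))
  y3 <- log(pmax(intensity[i + 1L], 1e-12))
  denom <- y1 - 2 * y2 + y3
  shift <- ifelse(abs(denom) > 1e-12, 0.5 * (y1 - y3) / denom, 0)
  shift <- pmax(pmin(shift, 0.5), -0.5)
  step <- (mz[i + 1L] - mz[i - 1L]) / 2
  list(mz = mz[i] + shift * step, intensity = intensity[i])
}

#' Write a run to mzML
#'
#' Emits standard mzML 1.1 through the `mzR`/proteowizard writer. Channels
#' are recorded in each scan's filter string; retention times are written in
#' seconds per the mzML convention. Batch metadata (sample id, group,
#' injection order, free-form keys) goes to a JSON sidecar
#' `<path>.meta.json`, which [read_run()] picks up automatically.
#'
#' @param run A [pci_run()].
#' @param path Output mzML path.
#' @param sidecar Write the metadata sidecar?
#' @return `path`, invisibly.
#' @export
write_run <- function(run, path, sidecar = TRUE) {
  stopifnot(inherits(run, "pci_run"))
  n <- length(run$spectra)
  chans <- run_channels(run)
  rts <- run_rts(run)
  ce <- c(low_energy = 2, high_energy = 30, lockmass = 2)[chans]
  pks <- lapply(run$spectra, function(sp) {
    if (any(diff(sp$mz) <= 0) && length(sp$mz) > 1L) stop("unsortable peaks")
    cbind(mz = sp$mz, intensity = sp$intensity)
  })
  npk <- vapply(pks, nrow, integer(1))
  hdr <- data.frame(
    seqNum = seq_len(n), acquisitionNum = seq_len(n), msLevel = 1L,
    polarity = 1L, peaksCount = npk,
    totIonCurrent = vapply(run$spectra, function(sp) sum(sp$intensity), numeric(1)),
    retentionTime = rts * 60,
    basePeakMZ = vapply(run$spectra, function(sp)
      if (length(sp$mz)) sp$mz[which.max(sp$intensity)] else 0, numeric(1)),
    basePeakIntensity = vapply(run$spectra, function(sp)
      if (length(sp$intensity)) max(sp$intensity) else 0, numeric(1)),
    collisionEnergy = unname(ce), ionisationEnergy = 0,
    lowMZ = vapply(run$spectra, function(sp)
      if (length(sp$mz)) min(sp$mz) else 0, numeric(1)),
    highMZ = vapply(run$spectra, function(sp)
      if (length(sp$mz)) max(sp$mz) else 0, numeric(1)),
    precursorScanNum = 0L, precursorMZ = 0, precursorCharge = 0L,
    precursorIntensity = 0, mergedScan = 0L, mergedResultScanNum = 0L,
    mergedResultStartScanNum = 0L, mergedResultEndScanNum = 0L,
    injectionTime = 0,
    filterString = sprintf("PCIQC channel=%s CE=%.1f", chans, ce),
    spectrumId = sprintf("scan=%d", seq_len(n)),
    centroided = vapply(run$spectra, `[[`, logical(1), "centroided"),
    ionMobilityDriftTime = NA_real_,
    isolationWindowTargetMZ = NA_real_, isolationWindowLowerOffset = NA_real_,
    isolationWindowUpperOffset = NA_real_,
    scanWindowLowerLimit = 50, scanWindowUpperLimit = 850,
    stringsAsFactors = FALSE
  )
  mzR::writeMSData(pks, path, header = hdr)
  if (sidecar) {
    meta <- list(sample_id = run$sample_id, group = run$group,
                 injection_order = run$injection_order,
                 metadata = run$metadata)
    jsonlite::write_json(meta, paste0(path, ".meta.json"), auto_unbox = TRUE)
  }
  invisible(path)
}

#' Read an mzML run
#'
#' Reads centroided or profile mzML (profile scans are centroided on load by
#' local-maximum picking with parabolic apex interpolation), assigns every
#' scan to an acquisition channel via `channel_rules`, converts retention
#' times to minutes, and attaches batch metadata from the `<path>.meta.json`
#' sidecar when present (explicit arguments win over the sidecar).
#'
#' @param path mzML file.
#' @param channel_rules See [default_channel_rules()].
#' @param sample_id,group,injection_order Optional metadata overrides.
#' @return A [pci_run()].
#' @export
read_run <- function(path, channel_rules = default_channel_rules(),
                     sample_id = NULL, group = NULL, injection_order = NULL) {
  stopifnot(file.exists(path))
  fh <- mzR::openMSfile(path)
  on.exit(mzR::close(fh), add = TRUE)
  hdr <- mzR::header(fh)
  if (!nrow(hdr)) stop("no spectra in '", path, "'")
  pks <- mzR::peaks(fh)
  if (is.matrix(pks)) pks <- list(pks)
  fs <- if ("filterString" %in% names(hdr)) hdr$filterString else rep(NA_character_, nrow(hdr))
  ce <- if ("collisionEnergy" %in% names(hdr)) hdr$collisionEnergy else rep(NA_real_, nrow(hdr))
  cent <- if ("centroided" %in% names(hdr)) hdr$centroided else rep(TRUE, nrow(hdr))
  spectra <- vector("list", nrow(hdr))
  for (i in seq_len(nrow(hdr))) {
    ch <- assign_channel(fs[i], ce[i], channel_rules)
    if (is.na(ch)) {
      stop("scan ", i, " of '", path, "' matches no channel rule")
    }
    m <- pks[[i]]
    mzv <- unname(m[, 1]); iv <- unname(m[, 2])
    if (isFALSE(cent[i]) && length(mzv) >= 3L) {
      cc <- centroid_profile(mzv, iv)
      mzv <- cc$mz; iv <- cc$intensity
    }
    spectra[[i]] <- pci_spectrum(hdr$retentionTime[i] / 60, ch, mzv, iv,
                                 centroided = TRUE)
  }
  meta <- list(sample_id = "sample", group = "unknown", injection_order = 1L,
               metadata = list())
  sc <- paste0(path, ".meta.json")
  if (file.exists(sc)) {
    j <- jsonlite::read_json(sc, simplifyVector = TRUE)
    meta$sample_id <- j$sample_id %||% meta$sample_id
    meta$group <- j$group %||% meta$group
    meta$injection_order <- j$injection_order %||% meta$injection_order
    meta$metadata <- as.list(j$metadata %||% list())
  }
  pci_run(spectra,
          sample_id = sample_id %||% meta$sample_id,
          group = group %||% meta$group,
          injection_order = injection_order %||% meta$injection_order,
          metadata = meta$metadata)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read or write a batch metadata sidecar table
#'
#' Tab-separated table with columns `path`, `sample_id`, `group`,
#' `injection_order`, `role` (`reference` or `sample`), describing one batch
#' of injections.
#'
#' @param path TSV path.
#' @param table Data frame with the columns above.
#' @return `read_batch_metadata` returns the data frame;
#'   `write_batch_metadata` returns `path` invisibly.
#' @export
read_batch_metadata <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("path", "sample_id", "group", "injection_order", "role")
  miss <- setdiff(need, names(tab))
  if (length(miss)) stop("metadata table missing column(s): ",
                         paste(miss, collapse = ", "))
  tab$injection_order <- as.integer(tab$injection_order)
  if (anyDuplicated(tab$injection_order)) {
    stop("injection_order values must be unique within a batch")
  }
  tab
}

#' @rdname read_batch_metadata
#' @export
write_batch_metadata <- function(table, path) {
  utils::write.table(table, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Single-point lock-mass correction
#'
#' Recalibrates the m/z axis against a continuously infused reference ion
#' (leucine enkephalin by default). The run is cut into intervals of
#' `interval` seconds; within each interval the observed reference m/z is
#' averaged over the `n_average` reference scans nearest the interval
#' midpoint, and the resulting multiplicative ppm correction is applied to
#' every peak of every spectrum in that interval. Reference scans are the
#' `lockmass` channel when present, otherwise the reference ion is located in
#' `low_energy` scans within `search_ppm`.
#'
#' Intervals where the reference is not found inherit the previous interval's
#' correction (logged); if the reference is never found the run is returned
#' unchanged with a warning.
#'
#' @param run A [pci_run()].
#' @param reference_mz Reference m/z ([pci_lockmass_mz] by default).
#' @param interval Correction interval in seconds.
#' @param n_average Number of reference scans averaged per interval.
#' @param search_ppm Search tolerance around the reference.
#' @return The corrected [pci_run()].
#' @export
lockmass_correct <- function(run, reference_mz = pci_lockmass_mz,
                             interval = 10, n_average = 3, search_ppm = 50) {
  stopifnot(inherits(run, "pci_run"), interval > 0, n_average >= 1)
  chans <- run_channels(run)
  ref_chan <- if (any(chans == "lockmass")) "lockmass" else "low_energy"
  win <- ppm_window(reference_mz, search_ppm)
  obs_rt <- numeric(0); obs_mz <- numeric(0)
  for (sp in run$spectra[chans == ref_chan]) {
    sel <- sp$mz >= win[1] & sp$mz <= win[2]
    if (any(sel)) {
      k <- which(sel)[which.max(sp$intensity[sel])]
      obs_rt <- c(obs_rt, sp$rt); obs_mz <- c(obs_mz, sp$mz[k])
    }
  }
  if (!length(obs_mz)) {
    warning("lock-mass reference ", reference_mz, " not found; run unchanged")
    return(run)
  }
  rts <- run_rts(run)
  iv_min <- interval / 60
  idx <- pmin(floor(rts / iv_min), floor(max(rts) / iv_min)) + 1L
  n_iv <- max(idx)
  factor_prev <- 1
  factors <- numeric(n_iv)
  for (j in seq_len(n_iv)) {
    lo <- (j - 1L) * iv_min; hi <- j * iv_min
    mid <- (lo + hi) / 2
    in_iv <- which(obs_rt >= lo & obs_rt < hi | (j == n_iv & obs_rt >= lo))
    if (length(in_iv)) {
      near <- in_iv[order(abs(obs_rt[in_iv] - mid))]
      near <- near[seq_len(min(n_average, length(near)))]
      factor_prev <- reference_mz / mean(obs_mz[near])
    } else {
      message(sprintf("lockmass: no reference in interval %d; carrying previous correction", j))
    }
    factors[j] <- factor_prev
  }
  spectra <- run$spectra
  for (i in seq_along(spectra)) {
    f <- factors[idx[i]]
    if (f != 1) spectra[[i]]$mz <- spectra[[i]]$mz * f
  }
  out <- run
  out$spectra <- spectra
  out
}
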