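#' Construct a single spectrum
#'
#' A centroided peak list at one retention time in one acquisition channel.
#' The two MSe-style channels are `low_energy` (2 eV, quasi-molecular ions)
#' and `high_energy` (15-40 V ramp, nonselective fragments); `lockmass` marks
#' dedicated reference scans when present.
#'
#' @param rt Retention time in minutes (>= 0).
#' @param channel One of `"low_energy"`, `"high_energy"`, `"lockmass"`.
#' @param mz Numeric vector of m/z values, strictly increasing.
#' @param intensity Numeric vector of intensities, finite and >= 0.
#' @param centroided Logical.
#' @return Object of class `pci_spectrum`.
#' @export
pci_spectrum <- function(rt, channel, mz = numeric(0), intensity = numeric(0),
                         centroided = TRUE) {
  channel <- match.arg(channel, c("low_energy", "high_energy", "lockmass"))
  stopifnot(length(rt) == 1L, rt >= 0, length(mz) == length(intensity))
  if (length(mz) > 1L && any(diff(mz) <= 0)) {
    o <- order(mz)
    mz <- mz[o]; intensity <- intensity[o]
    if (any(diff(mz) <= 0)) stop("m/z values must be strictly increasing")
  }
  if (length(intensity) && (any(!is.finite(intensity)) || any(intensity < 0))) {
    stop("intensities must be finite and non-negative")
  }
  structure(list(rt = rt, channel = channel, mz = mz, intensity = intensity,
                 centroided = isTRUE(centroided)),
            class = "pci_spectrum")
}

#' Construct an LC-MS run
#'
#' An ordered sequence of spectra plus batch metadata (sample id, group such
#' as `solvent`/`citrate`/`heparin`, and injection order within the batch).
#'
#' @param spectra List of [pci_spectrum()] objects, ordered by retention
#'   time (non-decreasing).
#' @param sample_id,group Character scalars.
#' @param injection_order Positive integer.
#' @param metadata Named list of free-form character metadata.
#' @return Object of class `pci_run`.
#' @export
pci_run <- function(spectra, sample_id = "sample", group = "unknown",
                    injection_order = 1L, metadata = list()) {
  stopifnot(is.list(spectra), length(spectra) >= 1L)
  rts <- vapply(spectra, `[[`, numeric(1), "rt")
  if (is.unsorted(rts)) stop("spectra must be ordered by retention time")
  chans <- vapply(spectra, `[[`, character(1), "channel")
  if (!any(chans == "low_energy")) {
    stop("run contains no low_energy spectra")
  }
  run <- structure(
    list(spectra = spectra, sample_id = sample_id, group = group,
         injection_order = as.integer(injection_order),
         metadata = metadata),
    class = "pci_run"
  )
  # scan-interval regularity check per channel (duty-cycle drops are a QC
  # observation, not an error)
  iv <- diff(rts[chans == "low_energy"])
  iv <- iv[iv > 0]
  if (length(iv) >= 3L) {
    cv <- stats::sd(iv) / mean(iv)
    if (is.finite(cv) && cv > 0.2) {
      message(sprintf("run '%s': low-energy scan interval CV = %.0f%% (> 20%%)",
                      sample_id, 100 * cv))
    }
  }
  run
}

run_channels <- function(run) {
  vapply(run$spectra, `[[`, character(1), "channel")
}

run_rts <- function(run, channel = NULL) {
  rts <- vapply(run$spectra, `[[`, numeric(1), "rt")
  if (!is.null(channel)) rts <- rts[run_channels(run) == channel]
  rts
}

channel_spectra <- function(run, channel) {
  run$spectra[run_channels(run) == channel]
}

#' @export
print.pci_run <- function(x, ...) {
  chans <- run_channels(x)
  rts <- run_rts(x)
  cat(sprintf("<pci_run> %s (group %s, injection %d)\n",
              x$sample_id, x$group, x$injection_order))
  cat(sprintf("  %d spectra, rt %.3f-%.3f min\n", length(x$spectra),
              min(rts), max(rts)))
  for (ch in unique(chans)) {
    cat(sprintf("  %s: %d scans\n", ch, sum(chans == ch)))
  }
  invisible(x)
}

#' @export
print.pci_spectrum <- function(x, ...) {
  cat(sprintf("<pci_spectrum> rt %.4f min, %s, %d peaks\n",
              x$rt, x$channel, length(x$mz)))
  invisible(x)
}
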