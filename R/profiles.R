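#' Construct a trace
#'
#' Time-resolved intensity of one target ion (one point per scan of the
#' channel). Masked points are `NA`.
#'
#' @param times Minutes, non-decreasing.
#' @param intensities Same length, >= 0 (or `NA` where masked).
#' @param target_mz,tol Target ion and its extraction tolerance (ppm, or Da
#'   when `tol_unit = "Da"`).
#' @param channel Acquisition channel the trace came from.
#' @param standard_id Label of the monitored standard or diagnostic ion.
#' @param tol_unit `"ppm"` or `"Da"`.
#' @return Object of class `pci_trace`.
#' @export
pci_trace <- function(times, intensities, target_mz, tol, channel,
                      standard_id = "", tol_unit = "ppm") {
  stopifnot(length(times) == length(intensities), !is.unsorted(times))
  structure(list(times = times, intensities = intensities,
                 target_mz = target_mz, tol = tol, tol_unit = tol_unit,
                 channel = channel, standard_id = standard_id),
            class = "pci_trace")
}

#' @export
print.pci_trace <- function(x, ...) {
  cat(sprintf("<pci_trace> %s m/z %.4f (+/- %g %s), %s, %d points\n",
              x$standard_id, x$target_mz, x$tol, x$tol_unit, x$channel,
              length(x$times)))
  invisible(x)
}

#' Extracted ion chromatogram
#'
#' Per scan of the requested channel, the summed intensity of all peaks
#' whose m/z falls inside the tolerance window around the target
#' ([ppm_window()] for ppm tolerances, `mz +/- tol` for absolute Da
#' tolerances). One point per scan.
#'
#' @param run A [pci_run()].
#' @param mz Target m/z.
#' @param tol Tolerance (default 10 ppm).
#' @param channel Channel to extract from.
#' @param tol_unit `"ppm"` or `"Da"`.
#' @param standard_id Label carried on the returned trace.
#' @return A [pci_trace()].
#' @export
extract_xic <- function(run, mz, tol = 10, channel = "low_energy",
                        tol_unit = c("ppm", "Da"), standard_id = "") {
  stopifnot(inherits(run, "pci_run"))
  tol_unit <- match.arg(tol_unit)
  sp <- channel_spectra(run, channel)
  if (!length(sp)) stop("run has no spectra in channel '", channel, "'")
  win <- if (tol_unit == "ppm") ppm_window(mz, tol) else c(mz - tol, mz + tol)
  times <- vapply(sp, `[[`, numeric(1), "rt")
  ints <- vapply(sp, function(s) {
    sum(s$intensity[s$mz >= win[1] & s$mz <= win[2]])
  }, numeric(1))
  pci_trace(times, ints, mz, tol, channel, standard_id, tol_unit)
}

#' Resample a trace onto a new time grid
#'
#' Linear interpolation between scan points; grid points outside the trace
#' span are masked (`NA`), never extrapolated.
#'
#' @param trace A [pci_trace()].
#' @param grid Time grid in minutes.
#' @return A [pci_trace()] on `grid`.
#' @export
resample_trace <- function(trace, grid) {
  stopifnot(inherits(trace, "pci_trace"))
  if (!length(grid)) stop("empty resampling grid")
  y <- stats::approx(trace$times, trace$intensities, xout = grid,
                     method = "linear", rule = 1)$y
  pci_trace(grid, y, trace$target_mz, trace$tol, trace$channel,
            trace$standard_id, trace$tol_unit)
}

# moving median with shrinking windows at the ends; NA segments are
# smoothed independently so masked points never leak into neighbours
moving_median <- function(x, window) {
  if (window %% 2 == 0) stop("smoothing window must be odd")
  if (window == 1L || length(x) < 3L) return(x)
  out <- x
  ok <- !is.na(x)
  r <- rle(ok)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  for (seg in which(r$values)) {
    i <- starts[seg]:ends[seg]
    if (length(i) >= 3L) {
      k <- min(window, length(i) - (1 - length(i) %% 2))
      out[i] <- stats::runmed(x[i], k, endrule = "median")
    }
  }
  out
}

#' Smooth a trace with a moving median
#'
#' @param trace A [pci_trace()].
#' @param window Odd window length in scans; 1 is the identity. Ends use
#'   shrinking windows.
#' @return A smoothed [pci_trace()].
#' @export
smooth_trace <- function(trace, window = 5L) {
  stopifnot(inherits(trace, "pci_trace"))
  tr <- trace
  tr$intensities <- moving_median(trace$intensities, as.integer(window))
  tr
}

#' Matrix-effect profile: sample vs reference ratio
#'
#' The sample trace is resampled onto the reference grid and divided by the
#' reference pointwise. Points where the reference is below `floor` (or
#' either trace is masked) are masked, never reported as zero or infinite.
#' A ratio below 1 is ion suppression, above 1 ion enhancement.
#'
#' @param sample,reference [pci_trace()]s of the same standard and channel.
#' @param floor Minimum reference intensity for a valid ratio (default 5x
#'   the simulator's additive baseline; tune to ~5x your background level).
#' @return Object of class `pci_profile` with elements `times`, `sample`,
#'   `reference`, `ratio` (`NA` = masked), `standard_id`.
#' @export
profile_ratio <- function(sample, reference, floor = 25) {
  stopifnot(inherits(sample, "pci_trace"), inherits(reference, "pci_trace"))
  if (nzchar(sample$standard_id) && nzchar(reference$standard_id) &&
      sample$standard_id != reference$standard_id) {
    stop("sample and reference traces monitor different standards")
  }
  if (sample$channel != reference$channel) {
    stop("sample and reference traces come from different channels")
  }
  if (min(sample$times) > max(reference$times) ||
      max(sample$times) < min(reference$times)) {
    stop("sample and reference time spans do not overlap")
  }
  s <- resample_trace(sample, reference$times)
  ratio <- s$intensities / reference$intensities
  ratio[is.na(s$intensities) | is.na(reference$intensities) |
          reference$intensities < floor] <- NA_real_
  structure(list(times = reference$times, sample = s$intensities,
                 reference = reference$intensities, ratio = ratio,
                 standard_id = sample$standard_id, floor = floor),
            class = "pci_profile")
}

#' @export
print.pci_profile <- function(x, ...) {
  ok <- !is.na(x$ratio)
  cat(sprintf("<pci_profile> %s: %d points (%d masked), ratio %.3g-%.3g\n",
              x$standard_id, length(x$ratio), sum(!ok),
              if (any(ok)) min(x$ratio[ok]) else NA,
              if (any(ok)) max(x$ratio[ok]) else NA))
  invisible(x)
}

#' Detect suppression and enhancement regions in a profile
#'
#' The ratio curve is median-smoothed, then maximal contiguous intervals
#' with smoothed ratio below `low` (ion suppression) or above `high` (ion
#' enhancement) are located. Same-kind regions separated by gaps of at most
#' `merge_gap` minutes are merged, then regions narrower than `min_width`
#' minutes are dropped. Masked points break intervals.
#'
#' @param profile A [profile_ratio()] result.
#' @param low,high Ratio thresholds, `0 < low < 1 < high`.
#' @param min_width Minimum region width, minutes.
#' @param merge_gap Maximum gap merged, minutes.
#' @param smooth_window Odd moving-median window applied to the ratio
#'   (scans); 1 disables smoothing.
#' @return Data frame of class `pci_regions`: `standard`, `kind`
#'   (`suppression`/`enhancement`), `start_min`, `end_min`, `extreme_ratio`
#'   (minimum inside for suppression, maximum for enhancement),
#'   `mean_ratio`.
#' @export
detect_regions <- function(profile, low = 0.7, high = 1.4,
                           min_width = 0.05, merge_gap = 0.03,
                           smooth_window = 5L) {
  stopifnot(inherits(profile, "pci_profile"))
  if (!(low > 0 && low < 1 && high > 1)) {
    stop("thresholds must satisfy 0 < low < 1 < high")
  }
  r <- moving_median(profile$ratio, as.integer(smooth_window))
  t <- profile$times
  state <- ifelse(is.na(r), "masked",
                  ifelse(r < low, "suppression",
                         ifelse(r > high, "enhancement", "none")))
  rl <- rle(state)
  ends <- cumsum(rl$lengths)
  starts <- ends - rl$lengths + 1L
  keep <- rl$values %in% c("suppression", "enhancement")
  regions <- data.frame(
    kind = rl$values[keep],
    start_min = t[starts[keep]], end_min = t[ends[keep]],
    i0 = starts[keep], i1 = ends[keep],
    stringsAsFactors = FALSE
  )
  # merge same-kind regions across small in-range gaps (masked gaps break)
  if (nrow(regions) > 1L) {
    merged <- regions[1, ]
    for (i in 2:nrow(regions)) {
      cur <- regions[i, ]
      last <- merged[nrow(merged), ]
      gap_states <- state[(last$i1 + 1L):(cur$i0 - 1L)]
      if (cur$kind == last$kind &&
          (cur$start_min - last$end_min) <= merge_gap &&
          !any(gap_states == "masked")) {
        merged[nrow(merged), c("end_min", "i1")] <- cur[, c("end_min", "i1")]
      } else {
        merged <- rbind(merged, cur)
      }
    }
    regions <- merged
  }
  if (nrow(regions)) {
    regions <- regions[(regions$end_min - regions$start_min) >= min_width, ,
                       drop = FALSE]
  }
  ex <- mn <- numeric(nrow(regions))
  for (i in seq_len(nrow(regions))) {
    rr <- r[regions$i0[i]:regions$i1[i]]
    rr <- rr[!is.na(rr)]
    ex[i] <- if (regions$kind[i] == "suppression") min(rr) else max(rr)
    mn[i] <- mean(rr)
  }
  out <- data.frame(standard = rep(profile$standard_id, nrow(regions)),
                    kind = regions$kind,
                    start_min = regions$start_min, end_min = regions$end_min,
                    extreme_ratio = ex, mean_ratio = mn,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("pci_regions", "data.frame")
  out
}

#' Spike-based matrix effect percentage
#'
#' `100 * response_in_matrix / response_in_solvent`: the conventional
#' post-extraction-spike comparison of an analyte's response with and
#' without matrix. 100% means no matrix effect; below 100% suppression,
#' above 100% enhancement.
#'
#' @param response_in_matrix,response_in_solvent Peak areas or intensities
#'   in the same units; solvent response must be > 0.
#' @return Percentage.
#' @export
matrix_effect_percent <- function(response_in_matrix, response_in_solvent) {
  if (any(response_in_solvent <= 0)) stop("solvent response must be > 0")
  100 * response_in_matrix / response_in_solvent
}
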