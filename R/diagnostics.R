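#' Average spectrum over a retention-time window
#'
#' Pools the centroid peaks of every scan of `channel` inside `window`,
#' clusters them on the m/z axis (peaks closer than `cluster_tol` Da belong
#' to one centroid cluster), and reports per cluster the intensity-weighted
#' mean m/z and the mean intensity per scan (summed cluster intensity
#' divided by the number of scans averaged).
#'
#' @param run A [pci_run()].
#' @param window Length-2 retention-time interval in minutes.
#' @param channel Channel to average.
#' @param cluster_tol Centroid clustering tolerance in Da.
#' @return A [pci_spectrum()] at the window midpoint.
#' @export
average_spectrum <- function(run, window, channel = "low_energy",
                             cluster_tol = 0.01) {
  stopifnot(inherits(run, "pci_run"), length(window) == 2L,
            window[1] <= window[2])
  sp <- channel_spectra(run, channel)
  rts <- vapply(sp, `[[`, numeric(1), "rt")
  sel <- sp[rts >= window[1] & rts <= window[2]]
  if (!length(sel)) stop("no ", channel, " scans in window [",
                         window[1], ", ", window[2], "] min")
  mz <- unlist(lapply(sel, `[[`, "mz"))
  it <- unlist(lapply(sel, `[[`, "intensity"))
  if (!length(mz)) {
    return(pci_spectrum(mean(window), channel))
  }
  o <- order(mz)
  mz <- mz[o]; it <- it[o]
  grp <- cumsum(c(1L, as.integer(diff(mz) > cluster_tol)))
  cmz <- vapply(split(seq_along(mz), grp), function(i) {
    stats::weighted.mean(mz[i], it[i])
  }, numeric(1))
  cint <- vapply(split(it, grp), sum, numeric(1)) / length(sel)
  pci_spectrum(mean(window), channel, mz = unname(cmz), intensity = unname(cint))
}

#' Phospholipid screen for a suppression region
#'
#' Tests whether a detected suppression region is explained by coeluting
#' glycerophosphocholine lipids by extracting the diagnostic phosphocholine
#' fragment (default 184.075 m/z, absolute +/- 0.025 Da window) from the
#' high-collision-energy channel and asking whether that fragment signal is
#' concentrated in the region. Two statistics are computed:
#' \describe{
#'   \item{enrichment}{mean fragment intensity inside the region divided by
#'     the mean outside.}
#'   \item{overlap_fraction}{fraction of the fragment's above-threshold time
#'     span (points above 10% of the fragment trace maximum) that falls
#'     inside the region.}
#' }
#' The verdict is phospholipid-consistent when `enrichment >= 3` and
#' `overlap_fraction >= 0.5`. Both statistics are invariant under global
#' intensity scaling of the run.
#'
#' @param run A [pci_run()] with a high-energy channel.
#' @param region One row of a [detect_regions()] table (or any list with
#'   `start_min`/`end_min`).
#' @param fragment_mz Diagnostic fragment m/z.
#' @param window Absolute extraction half-window, Da.
#' @param enrichment_min,overlap_min Verdict thresholds.
#' @return List of class `pci_phospholipid_screen`: `region`,
#'   `fragment_trace`, `enrichment`, `overlap_fraction`, `verdict`
#'   (logical).
#' @export
phospholipid_screen <- function(run, region, fragment_mz = 184.075,
                                window = 0.025, enrichment_min = 3,
                                overlap_min = 0.5) {
  stopifnot(inherits(run, "pci_run"))
  if (!any(run_channels(run) == "high_energy")) {
    stop("run has no high_energy channel; the fragment screen needs the ",
         "high-collision-energy scan function")
  }
  tr <- extract_xic(run, fragment_mz, tol = window, channel = "high_energy",
                    tol_unit = "Da", standard_id = "phosphocholine-fragment")
  inside <- tr$times >= region$start_min & tr$times <= region$end_min
  if (!any(inside) || all(inside)) {
    stop("region [", region$start_min, ", ", region$end_min,
         "] does not partition the run")
  }
  mean_in <- mean(tr$intensities[inside])
  mean_out <- mean(tr$intensities[!inside])
  enrichment <- if (mean_out > 0) mean_in / mean_out else
    (if (mean_in > 0) Inf else 1)
  thr <- 0.1 * max(tr$intensities)
  above <- tr$intensities > thr
  overlap <- if (any(above)) sum(above & inside) / sum(above) else 0
  structure(
    list(region = region, fragment_trace = tr, enrichment = enrichment,
         overlap_fraction = overlap,
         verdict = enrichment >= enrichment_min & overlap >= overlap_min),
    class = "pci_phospholipid_screen"
  )
}

#' @export
print.pci_phospholipid_screen <- function(x, ...) {
  cat(sprintf(
    "<phospholipid screen> [%.2f, %.2f] min: enrichment %.2f, overlap %.2f -> %s\n",
    x$region$start_min, x$region$end_min, x$enrichment, x$overlap_fraction,
    if (x$verdict) "phospholipid-consistent" else "negative"))
  invisible(x)
}

#' Detect polymer series in a spectrum
#'
#' Finds arithmetic m/z progressions (oligomer ladders such as the
#' polyethylene glycol 44 Da repeat) in a centroid spectrum. Peaks above
#' `min_rel_intensity` of the base peak are chained greedily: every pair of
#' peaks whose spacing lies in `repeat_range` seeds a candidate progression,
#' which is extended while a peak exists within `tol` of the next expected
#' member. Candidates with at least `min_members` members are accepted
#' longest-first (ties: higher summed intensity, then lower starting m/z),
#' their members removed from further chaining, and each accepted series is
#' refit by least squares of m/z on member index.
#'
#' @param spectrum A centroided [pci_spectrum()].
#' @param repeat_range Length-2 interval of candidate repeat units, Da.
#' @param tol Member-matching tolerance, Da.
#' @param min_members Minimum members per series.
#' @param min_rel_intensity Intensity cutoff relative to the base peak.
#' @return List of series; each has `member_mzs`, `member_intensities`,
#'   `spacing` (least-squares repeat, Da), `intercept`, `residual_rmsd`,
#'   `summed_intensity`. Empty list when nothing is found.
#' @export
detect_polymer_series <- function(spectrum, repeat_range = c(40, 50),
                                  tol = 0.02, min_members = 5L,
                                  min_rel_intensity = 0.01) {
  stopifnot(inherits(spectrum, "pci_spectrum"), spectrum$centroided,
            length(repeat_range) == 2L, repeat_range[1] < repeat_range[2])
  mz <- spectrum$mz; it <- spectrum$intensity
  if (length(mz) < min_members) return(list())
  keep <- it >= min_rel_intensity * max(it)
  mz <- mz[keep]; it <- it[keep]
  available <- rep(TRUE, length(mz))
  out <- list()
  repeat {
    best <- NULL
    idx_avail <- which(available)
    if (length(idx_avail) < min_members) break
    for (a in idx_avail) {
      partners <- idx_avail[mz[idx_avail] - mz[a] >= repeat_range[1] &
                              mz[idx_avail] - mz[a] <= repeat_range[2]]
      for (b in partners) {
        spacing <- mz[b] - mz[a]
        chain <- c(a, b)
        expected <- mz[b] + spacing
        repeat {
          cand <- idx_avail[abs(mz[idx_avail] - expected) <= tol]
          if (!length(cand)) break
          nxt <- cand[which.min(abs(mz[cand] - expected))]
          chain <- c(chain, nxt)
          expected <- mz[nxt] + spacing
        }
        if (length(chain) >= min_members) {
          cand_series <- list(chain = chain, n = length(chain),
                              sum_int = sum(it[chain]), start = mz[a])
          if (is.null(best) ||
              cand_series$n > best$n ||
              (cand_series$n == best$n && cand_series$sum_int > best$sum_int) ||
              (cand_series$n == best$n && cand_series$sum_int == best$sum_int &&
                 cand_series$start < best$start)) {
            best <- cand_series
          }
        }
      }
    }
    if (is.null(best)) break
    k <- seq_along(best$chain) - 1
    m <- mz[best$chain]
    fit <- stats::lm.fit(cbind(1, k), m)
    res <- sqrt(mean(fit$residuals^2))
    out[[length(out) + 1L]] <- list(
      member_mzs = m, member_intensities = it[best$chain],
      spacing = unname(fit$coefficients[2]),
      intercept = unname(fit$coefficients[1]),
      residual_rmsd = res, summed_intensity = best$sum_int
    )
    available[best$chain] <- FALSE
  }
  out
}

#' List the most intense coeluting features in a region
#'
#' Averages the low-energy spectrum inside the region and reports the
#' `top_n` most intense merged features with their apex retention time and
#' apex intensity — the raw material for manual (database) annotation of
#' putative coeluting compounds, which is deliberately left to the analyst.
#'
#' @param run A [pci_run()].
#' @param region Region with `start_min`/`end_min`.
#' @param top_n Number of features to report.
#' @param cluster_tol Feature merging tolerance, Da.
#' @return Data frame `mz`, `apex_rt`, `apex_intensity`, sorted by
#'   decreasing intensity. Empty for `top_n = 0` or an empty region.
#' @export
list_coeluting_features <- function(run, region, top_n = 10L,
                                    cluster_tol = 0.01) {
  empty <- data.frame(mz = numeric(0), apex_rt = numeric(0),
                      apex_intensity = numeric(0))
  if (top_n < 1L) return(empty)
  avg <- tryCatch(
    average_spectrum(run, c(region$start_min, region$end_min),
                     channel = "low_energy", cluster_tol = cluster_tol),
    error = function(e) NULL
  )
  if (is.null(avg) || !length(avg$mz)) return(empty)
  o <- order(avg$intensity, decreasing = TRUE)
  o <- o[seq_len(min(top_n, length(o)))]
  rows <- lapply(o, function(i) {
    tr <- extract_xic(run, avg$mz[i], tol = cluster_tol, tol_unit = "Da",
                      channel = "low_energy")
    inside <- tr$times >= region$start_min & tr$times <= region$end_min
    j <- which(inside)[which.max(tr$intensities[inside])]
    data.frame(mz = avg$mz[i], apex_rt = tr$times[j],
               apex_intensity = tr$intensities[j])
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
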