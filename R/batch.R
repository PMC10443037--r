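#' Relative standard deviation
#'
#' `100 * sd / mean` with the sample (n-1) standard deviation. Scale
#' invariant: `rsd(c * x) == rsd(x)` for any `c > 0`.
#'
#' @param values Numeric vector, length >= 2, positive mean.
#' @return RSD in percent.
#' @examples
#' rsd(c(1, 2, 3))  # 50
#' @export
rsd <- function(values) {
  if (length(values) < 2L) stop("rsd needs at least 2 values")
  m <- mean(values)
  if (m <= 0) stop("rsd needs a positive mean")
  100 * stats::sd(values) / m
}

#' Per-injection PCI metrics for one run
#'
#' For every standard in the panel (primary adduct): the median trace
#' intensity over the whole gradient (the per-injection "response"), the
#' fraction of the monitored time span inside detected suppression regions,
#' the number of regions, and the median sample/reference ratio.
#'
#' @param run A [pci_run()].
#' @param panel A `pci_panel`.
#' @param reference Reference run (solvent injection) or a named list of
#'   precomputed reference [pci_trace()]s keyed by standard name.
#' @param tol XIC tolerance, ppm.
#' @param floor,low,high,min_width,merge_gap,smooth_window Passed to
#'   [profile_ratio()] / [detect_regions()].
#' @return Data frame of class `pci_injection_metrics`, one row per
#'   standard: `sample_id`, `group`, `injection_order`, `standard`,
#'   `median_response`, `median_ratio`, `suppressed_fraction`,
#'   `n_regions`.
#' @export
injection_metrics <- function(run, panel = default_panel(), reference,
                              tol = 10, floor = 25, low = 0.7, high = 1.4,
                              min_width = 0.05, merge_gap = 0.03,
                              smooth_window = 5L) {
  stopifnot(inherits(run, "pci_run"))
  targets <- panel_targets(panel)
  ref_traces <- if (inherits(reference, "pci_run")) {
    traces <- lapply(seq_len(nrow(targets)), function(i) {
      extract_xic(reference, targets$mz[i], tol = tol,
                  standard_id = targets$name[i])
    })
    names(traces) <- targets$name
    traces
  } else reference
  rows <- lapply(seq_len(nrow(targets)), function(i) {
    nm <- targets$name[i]
    tr <- extract_xic(run, targets$mz[i], tol = tol, standard_id = nm)
    prof <- profile_ratio(tr, ref_traces[[nm]], floor = floor)
    regs <- detect_regions(prof, low = low, high = high,
                           min_width = min_width, merge_gap = merge_gap,
                           smooth_window = smooth_window)
    span <- diff(range(prof$times))
    supp <- regs[regs$kind == "suppression", , drop = FALSE]
    data.frame(
      sample_id = run$sample_id, group = run$group,
      injection_order = run$injection_order, standard = nm,
      median_response = stats::median(tr$intensities),
      median_ratio = stats::median(prof$ratio, na.rm = TRUE),
      suppressed_fraction =
        if (span > 0) sum(supp$end_min - supp$start_min) / span else 0,
      n_regions = nrow(regs),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  class(out) <- c("pci_injection_metrics", "data.frame")
  out
}

#' Detect injection-order buildup events in a response series
#'
#' Models the column-buildup signature: the per-injection response drops for
#' a few consecutive injections and then recovers to its initial level as
#' the accumulated material elutes. The rolling baseline for injection `i`
#' is the median of up to `baseline_n` preceding non-flagged injections
#' (initialised from the first injection, which is never flagged). An
#' injection is flagged when its value falls below `(1 - drop)` times the
#' baseline. A maximal span of at least `k` consecutive flagged injections
#' followed by a recovery (a later non-flagged injection) is a buildup
#' event; a flagged span running to the end of the series without recovery
#' is reported as drift instead.
#'
#' @param values Per-injection metric, in injection order.
#' @param drop Fractional drop defining a flagged injection.
#' @param k Minimum consecutive flagged injections per event.
#' @param baseline_n Baseline window, injections.
#' @return List: `events` (data frame `start`, `end` injection indices,
#'   `min_relative` lowest value/baseline inside), `drift` (logical),
#'   `flagged` (logical vector).
#' @export
detect_buildup <- function(values, drop = 0.25, k = 2L, baseline_n = 5L) {
  n <- length(values)
  if (n < 2L * k) stop("need at least 2*k injections, got ", n)
  flagged <- logical(n)
  rel <- numeric(n)
  base_vals <- values[1]
  rel[1] <- 1
  for (i in seq_len(n)[-1]) {
    base <- stats::median(utils::tail(base_vals, baseline_n))
    rel[i] <- values[i] / base
    flagged[i] <- values[i] < (1 - drop) * base
    if (!flagged[i]) base_vals <- c(base_vals, values[i])
  }
  rl <- rle(flagged)
  ends <- cumsum(rl$lengths)
  starts <- ends - rl$lengths + 1L
  ev <- data.frame(start = integer(0), end = integer(0),
                   min_relative = numeric(0))
  drift <- FALSE
  for (j in which(rl$values & rl$lengths >= k)) {
    if (ends[j] < n) {
      ev <- rbind(ev, data.frame(start = starts[j], end = ends[j],
                                 min_relative = min(rel[starts[j]:ends[j]])))
    } else {
      drift <- TRUE
    }
  }
  list(events = ev, drift = drift, flagged = flagged)
}

#' Assemble a batch report
#'
#' Runs [injection_metrics()] over a batch, computes within-group
#' (intragroup) RSD of each standard's per-injection response and the
#' min-max range of those RSDs across groups (intergroup range), detects
#' buildup/drift on the batch-median response series, and attaches QC
#' verdicts via [qc_evaluate()].
#'
#' @param runs List of [pci_run()]s (one batch; unique injection orders).
#' @param panel A `pci_panel`.
#' @param reference Reference run or precomputed reference traces.
#' @param thresholds Named list understood by [qc_evaluate()].
#' @param ... Passed to [injection_metrics()].
#' @return List of class `pci_batch_report`: `metrics` (stacked
#'   injection-metrics table), `rsd_table` (per group x standard),
#'   `intergroup_rsd_range`, `buildup`, `verdicts` (per run).
#' @export
batch_report <- function(runs, panel = default_panel(), reference,
                         thresholds = default_qc_thresholds(), ...) {
  stopifnot(is.list(runs), length(runs) >= 1L)
  ord <- vapply(runs, `[[`, integer(1), "injection_order")
  if (anyDuplicated(ord)) stop("injection_order values must be unique")
  runs <- runs[order(ord)]
  metrics <- do.call(rbind, lapply(runs, injection_metrics,
                                   panel = panel, reference = reference, ...))
  # intragroup RSD per (group, standard)
  groups <- unique(metrics$group)
  stds <- unique(metrics$standard)
  rsd_rows <- list()
  for (g in groups) {
    for (s in stds) {
      v <- metrics$median_response[metrics$group == g & metrics$standard == s]
      if (length(v) >= 2L && mean(v) > 0) {
        rsd_rows[[length(rsd_rows) + 1L]] <-
          data.frame(group = g, standard = s, n = length(v), rsd = rsd(v),
                     stringsAsFactors = FALSE)
      }
    }
  }
  rsd_table <- if (length(rsd_rows)) do.call(rbind, rsd_rows) else
    data.frame(group = character(0), standard = character(0),
               n = integer(0), rsd = numeric(0))
  inter_range <- if (nrow(rsd_table)) range(rsd_table$rsd) else c(NA_real_, NA_real_)
  # buildup on the per-injection batch-median response (across standards,
  # each standard normalised to its own batch median first)
  inj <- sort(unique(metrics$injection_order))
  resp <- vapply(inj, function(i) {
    m <- metrics[metrics$injection_order == i, ]
    med_by_std <- vapply(stds, function(s) {
      batch_med <- stats::median(
        metrics$median_response[metrics$standard == s])
      m$median_response[m$standard == s] / batch_med
    }, numeric(1))
    stats::median(med_by_std)
  }, numeric(1))
  buildup <- if (length(inj) >= 2L * thresholds$buildup_k) {
    detect_buildup(resp, drop = thresholds$buildup_drop,
                   k = thresholds$buildup_k)
  } else list(events = data.frame(start = integer(0), end = integer(0),
                                  min_relative = numeric(0)),
              drift = FALSE, flagged = rep(FALSE, length(inj)))
  report <- structure(
    list(metrics = metrics, rsd_table = rsd_table,
         intergroup_rsd_range = inter_range,
         response_series = data.frame(injection_order = inj,
                                      relative_response = resp),
         buildup = buildup, thresholds = thresholds),
    class = "pci_batch_report"
  )
  report$verdicts <- qc_evaluate(report, thresholds)
  report
}

#' Default QC thresholds
#'
#' @return Named list: `suppressed_fraction_max` (fail above),
#'   `rsd_warn` (%, warn above), `buildup_drop`, `buildup_k`.
#' @export
default_qc_thresholds <- function() {
  list(suppressed_fraction_max = 0.2, rsd_warn = 20,
       buildup_drop = 0.25, buildup_k = 2L)
}

#' QC verdict per injection
#'
#' Rules evaluated fail -> warn -> pass: an injection fails when any
#' standard's suppressed time fraction exceeds `suppressed_fraction_max` or
#' when the injection lies inside a detected buildup event; it warns when
#' its group's intragroup RSD exceeds `rsd_warn`; otherwise it passes.
#'
#' @param report A [batch_report()] (the `verdicts` element may be absent).
#' @param thresholds See [default_qc_thresholds()].
#' @return Data frame `injection_order`, `sample_id`, `verdict`, `reason`.
#' @export
qc_evaluate <- function(report, thresholds = default_qc_thresholds()) {
  need <- c("suppressed_fraction_max", "rsd_warn", "buildup_drop", "buildup_k")
  miss <- setdiff(need, names(thresholds))
  if (length(miss)) stop("missing threshold(s): ", paste(miss, collapse = ", "))
  metrics <- report$metrics
  inj <- sort(unique(metrics$injection_order))
  in_buildup <- rep(FALSE, length(inj))
  if (nrow(report$buildup$events)) {
    for (r in seq_len(nrow(report$buildup$events))) {
      ev <- report$buildup$events[r, ]
      in_buildup[seq_along(inj) >= ev$start & seq_along(inj) <= ev$end] <- TRUE
    }
  }
  rows <- lapply(seq_along(inj), function(ii) {
    i <- inj[ii]
    m <- metrics[metrics$injection_order == i, ]
    g <- m$group[1]
    grp_rsd <- report$rsd_table$rsd[report$rsd_table$group == g]
    verdict <- "pass"; reason <- ""
    if (any(m$suppressed_fraction > thresholds$suppressed_fraction_max)) {
      verdict <- "fail"
      worst <- m$standard[which.max(m$suppressed_fraction)]
      reason <- sprintf("suppressed_fraction %.2f (%s)",
                        max(m$suppressed_fraction), worst)
    } else if (in_buildup[ii]) {
      verdict <- "fail"; reason <- "inside buildup event"
    } else if (length(grp_rsd) && max(grp_rsd) > thresholds$rsd_warn) {
      verdict <- "warn"
      reason <- sprintf("intragroup RSD %.1f%%", max(grp_rsd))
    }
    data.frame(injection_order = i, sample_id = m$sample_id[1],
               verdict = verdict, reason = reason, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' @export
print.pci_batch_report <- function(x, ...) {
  cat(sprintf("<pci_batch_report> %d injections, %d standards\n",
              length(unique(x$metrics$injection_order)),
              length(unique(x$metrics$standard))))
  if (nrow(x$rsd_table)) {
    cat(sprintf("  intergroup RSD range: %.1f-%.1f%%\n",
                x$intergroup_rsd_range[1], x$intergroup_rsd_range[2]))
  }
  cat(sprintf("  buildup events: %d%s\n", nrow(x$buildup$events),
              if (x$buildup$drift) " (+ drift)" else ""))
  print(table(x$verdicts$verdict))
  invisible(x)
}
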