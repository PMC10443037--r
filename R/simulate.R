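#' Piecewise-linear gradient program
#'
#' @param times Breakpoint times in minutes, strictly increasing, starting
#'   at 0.
#' @param percent_b Organic fraction %B at each breakpoint, in `[0, 100]`.
#' @return Object of class `pci_gradient`.
#' @export
gradient_program <- function(times, percent_b) {
  stopifnot(length(times) == length(percent_b), length(times) >= 1L,
            times[1] == 0, !is.unsorted(times, strictly = TRUE),
            all(percent_b >= 0), all(percent_b <= 100))
  structure(list(times = times, percent_b = percent_b),
            class = "pci_gradient")
}

#' Default reversed-phase gradient
#'
#' 100% aqueous for the first 0.3 min, linear ramp to 100% organic at minute
#' 3, held 0.5 min, return to start in 0.1 min, re-equilibration to minute 5.
#'
#' @return A [gradient_program()].
#' @export
default_gradient <- function() {
  gradient_program(c(0, 0.3, 3, 3.5, 3.6, 5), c(0, 0, 100, 100, 0, 0))
}

#' Organic fraction at a time point
#'
#' Piecewise-linear interpolation of the gradient program, with constant
#' extrapolation after the last breakpoint.
#'
#' @param program A [gradient_program()].
#' @param t Time in minutes (>= 0); vectorised.
#' @return %B value(s).
#' @export
gradient_fraction <- function(program, t) {
  stopifnot(inherits(program, "pci_gradient"))
  if (any(t < 0)) stop("time must be >= 0")
  stats::approx(program$times, program$percent_b, xout = t, rule = 2)$y
}

#' Ion-suppression (or enhancement) event
#'
#' A multiplicative modulation of infused-standard response: at time `t` a
#' standard's intensity is scaled by `1 - depth * shape(t) * weight`. Depth 1
#' is total suppression; negative depth models enhancement.
#'
#' @param center Event center, minutes.
#' @param width Full width (at half depth for gaussian; total width for box),
#'   minutes, > 0.
#' @param depth Fraction in `[-1, 1]`; positive suppresses, negative enhances.
#' @param shape `"gaussian"` or `"box"`.
#' @param weights Optional named per-standard weights (default: all 1, i.e.
#'   the event affects every standard equally, as phospholipid suppression
#'   does).
#' @param modulated Should batch modulation patterns scale this event's
#'   depth (models injection-order buildup/elution cycles)?
#' @return Object of class `pci_event`.
#' @export
suppression_event <- function(center, width, depth, shape = c("gaussian", "box"),
                              weights = NULL, modulated = FALSE) {
  shape <- match.arg(shape)
  stopifnot(width > 0, depth >= -1, depth <= 1)
  structure(list(center = center, width = width, depth = depth, shape = shape,
                 weights = weights, modulated = isTRUE(modulated)),
            class = "pci_event")
}

event_shape <- function(event, t) {
  if (event$shape == "box") {
    as.numeric(t >= event$center - event$width / 2 &
                 t <= event$center + event$width / 2)
  } else {
    exp(-4 * log(2) * ((t - event$center) / event$width)^2)
  }
}

#' Synthetic-run scenario configuration
#'
#' Everything needed to simulate one postcolumn-infusion LC-MS run: the
#' standards panel with per-standard baseline intensities, the gradient, a
#' set of suppression/enhancement events, an optional phospholipid band
#' (precursor ions in the low-energy channel plus the phosphocholine
#' fragment in the high-energy channel), an optional polymer ladder, the
#' noise model, and an optional m/z error.
#'
#' Baseline intensity of each standard defaults to
#' `conc_mg_per_L * intensity_per_mg_L` (secondary adducts at 20%).
#' Noise is multiplicative log-normal with coefficient of variation
#' `noise_cv` (mean-corrected so the expected trace equals the noise-free
#' trace) plus a constant additive baseline on the persistent infused ions.
#' With `noise_cv = 0` and no events every standard's trace is exactly flat.
#'
#' @param standards A `pci_panel` (default [default_panel()]).
#' @param gradient A [gradient_program()].
#' @param events List of [suppression_event()]s.
#' @param phospholipid_band Optional list: `rt_window` (min), `fragment_mz`,
#'   `precursor_mzs`, `rel_intensities`, `intensity`.
#' @param polymer_ladder Optional list: `start_mz`, `repeat_da`, `n_members`,
#'   `rt_window`, `intensity`.
#' @param noise_cv Multiplicative CV (>= 0), default 5%.
#' @param baseline Additive baseline intensity on infused ions.
#' @param mass_error_ppm Constant m/z offset in ppm.
#' @param mass_drift_ppm Additional linear m/z drift (0 at t = 0 to this
#'   value at the end of the run), ppm.
#' @param scan_interval Per-channel scan interval in seconds, default 0.1.
#' @param run_length Run length in minutes, default 5.
#' @param lockmass_intensity Intensity of the continuously infused
#'   leucine-enkephalin reference ion in low-energy scans (not subject to
#'   matrix suppression: it is introduced by an independent sprayer).
#' @param intensity_per_mg_L Conversion from infusion concentration to
#'   baseline counts.
#' @return Object of class `pci_scenario`.
#' @export
scenario_config <- function(standards = default_panel(),
                            gradient = default_gradient(),
                            events = list(),
                            phospholipid_band = NULL,
                            polymer_ladder = NULL,
                            noise_cv = 0.05,
                            baseline = 5,
                            mass_error_ppm = 0,
                            mass_drift_ppm = 0,
                            scan_interval = 0.1,
                            run_length = 5,
                            lockmass_intensity = 5000,
                            intensity_per_mg_L = 4e4) {
  stopifnot(inherits(standards, "pci_panel"), nrow(standards) >= 1L,
            scan_interval > 0, noise_cv >= 0, run_length > 0)
  structure(
    list(standards = standards, gradient = gradient, events = events,
         phospholipid_band = phospholipid_band,
         polymer_ladder = polymer_ladder,
         noise_cv = noise_cv, baseline = baseline,
         mass_error_ppm = mass_error_ppm, mass_drift_ppm = mass_drift_ppm,
         scan_interval = scan_interval, run_length = run_length,
         lockmass_intensity = lockmass_intensity,
         intensity_per_mg_L = intensity_per_mg_L),
    class = "pci_scenario"
  )
}

# multiplicative log-normal noise, mean-corrected: E[noise] = 1, sd/mean = cv
mult_noise <- function(n, cv) {
  if (cv <= 0) return(rep(1, n))
  sigma <- sqrt(log(1 + cv^2))
  exp(stats::rnorm(n, mean = -sigma^2 / 2, sd = sigma))
}

suppression_factor <- function(events, t, standard_name) {
  f <- rep(1, length(t))
  for (ev in events) {
    w <- 1
    if (!is.null(ev$weights)) {
      w <- if (standard_name %in% names(ev$weights)) ev$weights[[standard_name]] else 0
    }
    f <- f * pmax(0, 1 - ev$depth * w * event_shape(ev, t))
  }
  f
}

#' Simulate one postcolumn-infusion run
#'
#' Each infused standard produces a constant-in-time ion at its adduct m/z
#' whose intensity is `baseline_intensity * prod(1 - depth_e(t)) * noise +
#' additive baseline`. The phospholipid band adds its precursor ions to the
#' low-energy channel and the phosphocholine fragment to the high-energy
#' channel inside its retention window; the polymer ladder adds its members
#' to low-energy spectra in its window. Standards are mirrored into the
#' high-energy channel at 10% intensity (surviving quasi-molecular signal
#' under the energy ramp), suppressed identically. Identical
#' `(config, seed)` give bit-identical runs.
#'
#' @param config A [scenario_config()].
#' @param seed Integer RNG seed.
#' @param sample_id,group,injection_order Run metadata.
#' @return A [pci_run()].
#' @export
simulate_run <- function(config, seed = 1L, sample_id = "sim",
                         group = "unknown", injection_order = 1L) {
  stopifnot(inherits(config, "pci_scenario"))
  if (!nrow(config$standards)) stop("standards panel is empty")
  set.seed(seed)
  dt <- config$scan_interval / 60
  t_low <- seq(0, config$run_length, by = dt)
  t_high <- t_low + dt / 2
  t_high <- t_high[t_high <= config$run_length]
  pan <- config$standards

  ion_tab <- function(channel, t) {
    # rows: one per ion; columns of the returned matrix: scans
    mzs <- numeric(0); mat <- NULL; persistent <- logical(0)
    add_ion <- function(mz, y, persist) {
      mzs <<- c(mzs, mz)
      mat <<- rbind(mat, y)
      persistent <<- c(persistent, persist)
    }
    scale <- if (channel == "low_energy") 1 else 0.1
    for (i in seq_len(nrow(pan))) {
      base <- pan$conc_mg_per_L[i] * config$intensity_per_mg_L *
        (if (pan$primary[i]) 1 else 0.2) * scale
      y <- base * suppression_factor(config$events, t, pan$name[i])
      add_ion(pan$mz[i], y, TRUE)
    }
    if (channel == "low_energy" && config$lockmass_intensity > 0) {
      add_ion(pci_lockmass_mz, rep(config$lockmass_intensity, length(t)), TRUE)
    }
    band <- config$phospholipid_band
    if (!is.null(band)) {
      ctr <- mean(band$rt_window)
      fwhm <- 0.7 * diff(band$rt_window)
      shp <- exp(-4 * log(2) * ((t - ctr) / fwhm)^2)
      if (channel == "low_energy") {
        rel <- band$rel_intensities
        for (k in seq_along(band$precursor_mzs)) {
          add_ion(band$precursor_mzs[k], band$intensity * rel[k] * shp, FALSE)
        }
      } else {
        add_ion(band$fragment_mz, band$intensity * shp, FALSE)
      }
    }
    lad <- config$polymer_ladder
    if (!is.null(lad) && channel == "low_energy") {
      inside <- as.numeric(t >= lad$rt_window[1] & t <= lad$rt_window[2])
      for (k in seq_len(lad$n_members) - 1L) {
        add_ion(lad$start_mz + k * lad$repeat_da, lad$intensity * inside, FALSE)
      }
    }
    o <- order(mzs)
    list(mz = mzs[o], y = mat[o, , drop = FALSE], persistent = persistent[o])
  }

  build_spectra <- function(channel, t) {
    tab <- ion_tab(channel, t)
    n_ion <- length(tab$mz); n_scan <- length(t)
    noise <- matrix(mult_noise(n_ion * n_scan, config$noise_cv), n_ion, n_scan)
    y <- tab$y * noise + config$baseline * tab$persistent
    drift <- config$mass_error_ppm + config$mass_drift_ppm * t / config$run_length
    lapply(seq_len(n_scan), function(s) {
      keep <- y[, s] >= 0.5
      pci_spectrum(t[s], channel,
                   mz = tab$mz[keep] * (1 + drift[s] * 1e-6),
                   intensity = y[keep, s])
    })
  }

  sp <- c(build_spectra("low_energy", t_low),
          build_spectra("high_energy", t_high))
  rts <- vapply(sp, `[[`, numeric(1), "rt")
  pci_run(sp[order(rts)], sample_id = sample_id, group = group,
          injection_order = injection_order,
          metadata = list(simulated = "true", seed = as.character(seed)))
}

#' Batch modulation pattern
#'
#' Per-injection multipliers applied to the depth of events flagged
#' `modulated = TRUE`, modelling column buildup/elution cycles across a
#' batch.
#'
#' @param pattern Numeric multipliers, one per injection, >= 0.
#' @return Object of class `pci_modulation`.
#' @export
batch_modulation <- function(pattern) {
  stopifnot(is.numeric(pattern), length(pattern) >= 1L, all(pattern >= 0))
  structure(list(pattern = pattern, n_injections = length(pattern)),
            class = "pci_modulation")
}

#' Simulate a batch of injections
#'
#' Injection `i` scales the depth of every `modulated` event by
#' `modulation$pattern[i]` (clamped to `[-1, 0.999]`); per-run seeds are
#' derived deterministically from the master seed so different master seeds
#' give different noise realisations over the same event structure.
#'
#' @param config A [scenario_config()].
#' @param modulation A [batch_modulation()]; its length fixes the number of
#'   injections.
#' @param seed Master seed.
#' @param group Group label stamped on every run.
#' @return List of [pci_run()]s with `injection_order` 1..n.
#' @export
simulate_batch <- function(config, modulation, seed = 1L, group = "batch") {
  stopifnot(inherits(config, "pci_scenario"),
            inherits(modulation, "pci_modulation"))
  n <- modulation$n_injections
  lapply(seq_len(n), function(i) {
    cfg <- config
    cfg$events <- lapply(config$events, function(ev) {
      if (ev$modulated) {
        ev$depth <- max(-1, min(0.999, ev$depth * modulation$pattern[i]))
      }
      ev
    })
    simulate_run(cfg, seed = (seed + 7919L * i) %% 2147483647L,
                 sample_id = sprintf("inj%02d", i), group = group,
                 injection_order = i)
  })
}

#' Library of named scenario presets
#'
#' Fully specified scenarios mirroring the situations the toolkit is built
#' to catch:
#' \describe{
#'   \item{solvent}{Null reference injection: no events, no band, no ladder.}
#'   \item{ppt_plasma}{Protein-precipitated plasma: a deep suppression box
#'     over 2.75-3.25 min caused by a late-eluting phospholipid band, whose
#'     184.07 phosphocholine fragment appears in the high-energy channel.}
#'   \item{ostro_plasma}{The same plasma after phospholipid-removal
#'     cleanup: band attenuated 20-fold, residual suppression shallow.}
#'   \item{heparin}{Plasma from heparin collection tubes: polyethylene
#'     glycol ladder (44.0262 Da repeat) around 1.5 min with a co-located
#'     suppression area.}
#'   \item{citrate}{Plasma from citrate tubes: no polymer contamination.}
#'   \item{batch_buildup}{A broad, shallow suppression event flagged for
#'     injection-order modulation, for simulating phospholipid buildup and
#'     elution cycles across a batch.}
#' }
#'
#' @param name Preset name; omit to get the full named list.
#' @param ... Overrides passed to [scenario_config()] (e.g. `noise_cv`,
#'   `scan_interval`).
#' @return A [scenario_config()], or a named list of them.
#' @export
scenario_library <- function(name = NULL, ...) {
  presets <- list(
    solvent = function(...) scenario_config(...),
    ppt_plasma = function(...) scenario_config(
      events = list(suppression_event(3.0, 0.5, 0.8, shape = "box")),
      phospholipid_band = list(
        rt_window = c(2.75, 3.25), fragment_mz = 184.0733,
        precursor_mzs = c(496.3399, 520.3403, 524.3716, 758.5699),
        rel_intensities = c(1, 0.4, 0.6, 0.8), intensity = 5e4),
      ...),
    ostro_plasma = function(...) scenario_config(
      events = list(suppression_event(3.0, 0.5, 0.2, shape = "box")),
      phospholipid_band = list(
        rt_window = c(2.75, 3.25), fragment_mz = 184.0733,
        precursor_mzs = c(496.3399, 520.3403, 524.3716, 758.5699),
        rel_intensities = c(1, 0.4, 0.6, 0.8), intensity = 2.5e3),
      ...),
    heparin = function(...) scenario_config(
      events = list(suppression_event(1.5, 0.4, 0.7, shape = "gaussian")),
      polymer_ladder = list(start_mz = 300.10, repeat_da = 44.0262,
                            n_members = 10, rt_window = c(1.3, 1.7),
                            intensity = 2e4),
      ...),
    citrate = function(...) scenario_config(...),
    batch_buildup = function(...) scenario_config(
      events = list(suppression_event(2.5, 3.0, 0.2, shape = "box",
                                      modulated = TRUE)),
      ...)
  )
  if (is.null(name)) {
    return(lapply(presets, function(f) f()))
  }
  if (!name %in% names(presets)) {
    stop("unknown scenario '", name, "'; available: ",
         paste(names(presets), collapse = ", "))
  }
  presets[[name]](...)
}
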