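# shared fixtures and independent oracles, built in code at test time

# independent brute-force XIC oracle: explicit loop over every peak of
# every spectrum, no shared code with extract_xic
oracle_xic <- function(run, mz, tol_ppm, channel) {
  lo <- mz * (1 - tol_ppm * 1e-6)
  hi <- mz * (1 + tol_ppm * 1e-6)
  times <- c(); ints <- c()
  for (sp in run$spectra) {
    if (sp$channel != channel) next
    total <- 0
    for (j in seq_along(sp$mz)) {
      if (sp$mz[j] >= lo && sp$mz[j] <= hi) total <- total + sp$intensity[j]
    }
    times <- c(times, sp$rt)
    ints <- c(ints, total)
  }
  list(times = times, intensities = ints)
}

# small random two-channel run with arbitrary peak lists
random_run <- function(seed, n_scans = 8, max_peaks = 12) {
  set.seed(seed)
  spectra <- list()
  rt <- 0
  for (i in seq_len(n_scans)) {
    rt <- rt + 0.01 + stats::runif(1, 0, 0.001)
    ch <- if (i %% 2 == 1) "low_energy" else "high_energy"
    np <- sample(0:max_peaks, 1)
    mz <- sort(stats::runif(np, 60, 840))
    spectra[[i]] <- pci_spectrum(rt, ch, mz, stats::runif(np, 0, 1e5))
  }
  pci_run(spectra, sample_id = sprintf("rnd%d", seed))
}

# quick scenario: paper-condition defaults but shorter where a test only
# needs structure, not the full 5-min / 0.1-s problem size
quick_scenario <- function(name = "solvent", run_length = 1, ...) {
  scenario_library(name, run_length = run_length, ...)
}

# flat-noise-free variant for exactness checks
exact_scenario <- function(name = "solvent", ...) {
  scenario_library(name, noise_cv = 0, ...)
}
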