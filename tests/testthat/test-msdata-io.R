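test_that("spectrum and run constructors enforce the data model", {
  expect_error(pci_spectrum(0.5, "low_energy", c(100, 100), c(1, 2)),
               "strictly increasing")
  expect_error(pci_spectrum(0.5, "low_energy", 100, -1), "non-negative")
  s1 <- pci_spectrum(0.2, "low_energy", 100, 5)
  s2 <- pci_spectrum(0.1, "low_energy", 100, 5)
  expect_error(pci_run(list(s1, s2)), "ordered")
  expect_error(pci_run(list(pci_spectrum(0.1, "high_energy", 100, 1))),
               "low_energy")
})

test_that("mzML round-trip is the identity on the run model", {
  dir <- withr::local_tempdir()
  for (seed in 1:5) {
    run <- random_run(seed)
    f <- file.path(dir, sprintf("r%d.mzML", seed))
    write_run(run, f)
    r2 <- read_run(f)
    expect_equal(length(r2$spectra), length(run$spectra))
    for (i in seq_along(run$spectra)) {
      expect_equal(r2$spectra[[i]]$mz, run$spectra[[i]]$mz, tolerance = 1e-9)
      expect_equal(r2$spectra[[i]]$intensity, run$spectra[[i]]$intensity,
                   tolerance = 1e-9)
      expect_equal(r2$spectra[[i]]$rt, run$spectra[[i]]$rt, tolerance = 1e-9)
      expect_identical(r2$spectra[[i]]$channel, run$spectra[[i]]$channel)
    }
  }
})

test_that("empty peak lists and metadata survive the round-trip", {
  run <- pci_run(list(pci_spectrum(0.1, "low_energy"),
                      pci_spectrum(0.2, "high_energy"),
                      pci_spectrum(0.3, "low_energy", 150.1, 42)),
                 sample_id = "qc01", group = "heparin", injection_order = 9L,
                 metadata = list(operator = "x", column_lot = "L1"))
  f <- tempfile(fileext = ".mzML")
  r2 <- read_run(write_run(run, f))
  expect_length(r2$spectra[[1]]$mz, 0L)
  expect_equal(r2$spectra[[3]]$intensity, 42)
  expect_identical(r2$sample_id, "qc01")
  expect_identical(r2$group, "heparin")
  expect_identical(r2$injection_order, 9L)
  expect_identical(r2$metadata$column_lot, "L1")
})

test_that("retention times are stored in seconds on disk, minutes in memory", {
  run <- pci_run(list(pci_spectrum(2, "low_energy", 100, 1)))
  f <- tempfile(fileext = ".mzML")
  write_run(run, f)
  fh <- mzR::openMSfile(f)
  expect_equal(mzR::header(fh)$retentionTime, 120)
  mzR::close(fh)
  expect_equal(read_run(f)$spectra[[1]]$rt, 2)
})

test_that("channel rules reject files without a low-energy function", {
  run <- simulate_run(exact_scenario(run_length = 0.05), seed = 1)
  f <- tempfile(fileext = ".mzML")
  write_run(run, f)
  rules <- default_channel_rules(low_pattern = "no-such-channel-tag",
                                 high_pattern = "channel=",
                                 ce_low_max = -1)
  expect_error(read_run(f, channel_rules = rules), "low_energy")
})

test_that("lock-mass correction removes a constant ppm offset", {
  cfg <- exact_scenario(run_length = 1, mass_error_ppm = 5)
  run <- simulate_run(cfg, seed = 4)
  corr <- lockmass_correct(run)
  res <- vapply(corr$spectra, function(s) {
    if (s$channel != "low_energy") return(NA_real_)
    i <- which.min(abs(s$mz - pci_lockmass_mz))
    abs(s$mz[i] / pci_lockmass_mz - 1) * 1e6
  }, numeric(1))
  expect_lt(max(res, na.rm = TRUE), 0.1)
  # zero mass error: output identical to input
  clean <- simulate_run(exact_scenario(run_length = 0.2), seed = 5)
  expect_equal(lockmass_correct(clean), clean, tolerance = 1e-12)
})

test_that("stepwise correction bounds residuals under linear drift", {
  cfg <- exact_scenario(run_length = 1, mass_drift_ppm = 10)
  run <- simulate_run(cfg, seed = 6)
  corr <- lockmass_correct(run, interval = 10, n_average = 3)
  res <- vapply(corr$spectra, function(s) {
    if (s$channel != "low_energy") return(NA_real_)
    i <- which.min(abs(s$mz - pci_lockmass_mz))
    abs(s$mz[i] / pci_lockmass_mz - 1) * 1e6
  }, numeric(1))
  # 10 ppm/min drift over 10-s intervals: residual < drift across an interval
  expect_lt(max(res, na.rm = TRUE), 10 / 6 + 0.1)
})

test_that("lock-mass correction is idempotent and degrades gracefully", {
  run <- simulate_run(quick_scenario(mass_error_ppm = 3), seed = 7)
  c1 <- lockmass_correct(run)
  c2 <- lockmass_correct(c1)
  d <- max(mapply(function(a, b) {
    if (!length(a$mz)) return(0)
    max(abs(a$mz / b$mz - 1)) * 1e6
  }, c1$spectra, c2$spectra))
  expect_lt(d, 0.05)
  # reference absent everywhere: warning, run unchanged
  no_lock <- simulate_run(exact_scenario(run_length = 0.1,
                                         lockmass_intensity = 0), seed = 8)
  expect_warning(out <- lockmass_correct(no_lock), "not found")
  expect_identical(out, no_lock)
})

test_that("batch metadata sidecar tables round-trip and validate", {
  tab <- data.frame(path = c("a.mzML", "b.mzML"), sample_id = c("s1", "s2"),
                    group = "urine", injection_order = 1:2,
                    role = c("reference", "sample"))
  f <- tempfile(fileext = ".tsv")
  write_batch_metadata(tab, f)
  r <- read_batch_metadata(f)
  expect_equal(r$sample_id, tab$sample_id)
  tab2 <- tab; tab2$injection_order <- c(1L, 1L)
  f2 <- tempfile(fileext = ".tsv")
  write_batch_metadata(tab2, f2)
  expect_error(read_batch_metadata(f2), "unique")
})

test_that("profile-mode peak lists are centroided on load", {
  # gaussian-ish profile peak sampled on a regular m/z comb
  mzg <- seq(499.9, 500.1, by = 0.005)
  prof <- 1000 * exp(-((mzg - 500.002) / 0.02)^2)
  cc <- pciqc:::centroid_profile(mzg, prof)
  expect_equal(length(cc$mz), 1L)
  expect_equal(cc$mz, 500.002, tolerance = 5e-4)
})
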