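test_that("spectrum averaging merges centroids within the cluster tolerance", {
  s1 <- pci_spectrum(1.0, "low_energy", c(100.000, 200.0), c(10, 4))
  s2 <- pci_spectrum(1.1, "low_energy", c(100.005, 200.0), c(30, 4))
  run <- pci_run(list(s1, s2))
  # single-scan window returns that spectrum
  one <- average_spectrum(run, c(0.95, 1.05))
  expect_equal(one$mz, s1$mz)
  expect_equal(one$intensity, s1$intensity)
  # two identical spectra: same peaks, same intensities
  run2 <- pci_run(list(s1, pci_spectrum(1.1, "low_energy", s1$mz, s1$intensity)))
  avg2 <- average_spectrum(run2, c(0.9, 1.2))
  expect_equal(avg2$mz, s1$mz)
  expect_equal(avg2$intensity, s1$intensity)
  # +0.005 Da shifted pair merges at the intensity-weighted mean m/z
  avg <- average_spectrum(run, c(0.9, 1.2))
  expect_length(avg$mz, 2L)
  expect_equal(avg$mz[1], (100.000 * 10 + 100.005 * 30) / 40)
  expect_equal(avg$intensity, c(20, 4))
  expect_error(average_spectrum(run, c(5, 6)), "no low_energy scans")
})

test_that("phospholipid screen separates band from null scenarios", {
  reg <- data.frame(start_min = 2.75, end_min = 3.25)
  ppt <- simulate_run(scenario_library("ppt_plasma"), seed = 41)
  scr <- phospholipid_screen(ppt, reg)
  expect_gte(scr$enrichment, 3)
  expect_gte(scr$overlap_fraction, 0.5)
  expect_true(scr$verdict)
  # same run, region placed away from the band
  off <- phospholipid_screen(ppt, data.frame(start_min = 0.5, end_min = 1.0))
  expect_false(off$verdict)
  # solvent: no fragment signal concentrated anywhere
  solv <- simulate_run(scenario_library("solvent"), seed = 42)
  nul <- phospholipid_screen(solv, reg)
  expect_false(nul$verdict)
  expect_equal(nul$enrichment, 1, tolerance = 0.25)
})

test_that("screen enrichment is invariant under global intensity scaling", {
  run <- simulate_run(quick_scenario("ppt_plasma", run_length = 5), seed = 43)
  scaled <- run
  scaled$spectra <- lapply(run$spectra, function(s) {
    s$intensity <- s$intensity * 37.5
    s
  })
  reg <- data.frame(start_min = 2.75, end_min = 3.25)
  a <- phospholipid_screen(run, reg)
  b <- phospholipid_screen(scaled, reg)
  expect_equal(a$enrichment, b$enrichment)
  expect_equal(a$overlap_fraction, b$overlap_fraction)
})

test_that("screen requires the high-collision-energy channel", {
  low_only <- pci_run(list(pci_spectrum(1, "low_energy", 100, 1)))
  expect_error(phospholipid_screen(low_only,
                                   data.frame(start_min = 0.5, end_min = 1)),
               "high_energy")
})

test_that("a clean oligomer ladder is found with exact spacing", {
  mz <- 300.10 + (0:9) * 44.0262
  sp <- pci_spectrum(1.5, "low_energy", mz, rep(1000, 10))
  ser <- detect_polymer_series(sp)
  expect_length(ser, 1L)
  expect_length(ser[[1]]$member_mzs, 10L)
  # least squares on a noise-free ladder is exact
  expect_equal(ser[[1]]$spacing, 44.0262, tolerance = 1e-6)
  expect_lt(ser[[1]]$residual_rmsd, 1e-9)
})

test_that("series spacing is shift-invariant", {
  mz <- 300.10 + (0:7) * 44.0262
  a <- detect_polymer_series(pci_spectrum(1, "low_energy", mz, rep(1, 8)))
  b <- detect_polymer_series(pci_spectrum(1, "low_energy", mz + 123.456,
                                          rep(1, 8)))
  expect_equal(a[[1]]$spacing, b[[1]]$spacing)
})

test_that("random peaks alone rarely produce a series", {
  hits <- 0L
  for (seed in 1:20) {
    set.seed(seed)
    mz <- sort(runif(50, 100, 800))
    sp <- pci_spectrum(1, "low_energy", mz, runif(50, 500, 1500))
    if (length(detect_polymer_series(sp)) > 0) hits <- hits + 1L
  }
  expect_lte(hits, 1L)
})

test_that("the ladder survives superimposed random peaks", {
  for (seed in 1:5) {
    set.seed(seed)
    ladder <- 300.10 + (0:9) * 44.0262
    noise <- runif(50, 100, 800)
    mz <- c(ladder, noise)
    it <- c(rep(1000, 10), runif(50, 500, 1500))
    o <- order(mz)
    sp <- pci_spectrum(1, "low_energy", mz[o], it[o])
    ser <- detect_polymer_series(sp)
    expect_gte(length(ser), 1L)
    recovered <- sum(vapply(ladder, function(m) {
      any(abs(ser[[1]]$member_mzs - m) < 0.005)
    }, logical(1)))
    expect_gte(recovered, 9L)
    expect_equal(ser[[1]]$spacing, 44.0262, tolerance = 0.01)
  }
})

test_that("the heparin scenario's averaged spectrum reveals the PEG series", {
  hep <- simulate_run(scenario_library("heparin"), seed = 44)
  avg <- average_spectrum(hep, c(1.3, 1.7))
  ser <- detect_polymer_series(avg)
  expect_gte(length(ser), 1L)
  expect_equal(ser[[1]]$spacing, 44.0262, tolerance = 0.005)
  # citrate plasma shows no such series
  cit <- simulate_run(scenario_library("citrate"), seed = 44)
  expect_length(detect_polymer_series(average_spectrum(cit, c(1.3, 1.7))), 0L)
})

test_that("coeluting-feature listing ranks band precursors first", {
  ppt <- simulate_run(scenario_library("ppt_plasma"), seed = 45)
  reg <- data.frame(start_min = 2.75, end_min = 3.25)
  feats <- list_coeluting_features(ppt, reg, top_n = 4)
  band <- scenario_library("ppt_plasma")$phospholipid_band$precursor_mzs
  expect_equal(nrow(feats), 4L)
  expect_true(all(vapply(feats$mz, function(m) any(abs(band - m) < 0.01),
                         logical(1))))
  expect_true(all(feats$apex_rt >= 2.75 & feats$apex_rt <= 3.25))
  expect_equal(nrow(list_coeluting_features(ppt, reg, top_n = 0)), 0L)
  # solvent: only the infused ions (standards + lock mass) appear
  solv <- simulate_run(scenario_library("solvent"), seed = 46)
  fs <- list_coeluting_features(solv, reg, top_n = 20)
  infused <- c(default_panel()$mz, pci_lockmass_mz)
  expect_true(all(vapply(fs$mz, function(m) any(abs(infused - m) < 0.02),
                         logical(1))))
})
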