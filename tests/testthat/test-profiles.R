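test_that("extract_xic sums peaks inside the tolerance window", {
  run <- pci_run(list(pci_spectrum(0.1, "low_energy",
                                   c(499.99, 500.0, 500.004, 501.0),
                                   c(7, 10, 3, 100))))
  tr <- extract_xic(run, 500.0, tol = 10)
  expect_length(tr$intensities, 1L)
  expect_equal(tr$intensities, 13)  # 500.0 and 500.004; 499.99 is -20 ppm
  expect_error(extract_xic(run, 500, channel = "high_energy"), "channel")
})

test_that("extract_xic matches the brute-force all-peaks oracle", {
  for (seed in 1:20) {
    run <- random_run(seed)
    mz <- runif(1, 80, 800)
    tol <- runif(1, 1, 5000)
    ch <- sample(c("low_energy", "high_energy"), 1)
    got <- extract_xic(run, mz, tol = tol, channel = ch)
    want <- oracle_xic(run, mz, tol, ch)
    expect_identical(got$intensities, want$intensities)
    expect_identical(got$times, want$times)
  }
})

test_that("resampling interpolates linearly and masks outside the span", {
  tr <- pci_trace(c(1, 2, 3), c(10, 20, 40), 500, 10, "low_energy", "s")
  expect_equal(resample_trace(tr, c(1, 2, 3))$intensities, c(10, 20, 40))
  expect_equal(resample_trace(tr, 2.5)$intensities, 30)  # midpoint mean
  expect_true(is.na(resample_trace(tr, 3.5)$intensities))
  expect_error(resample_trace(tr, numeric(0)), "empty")
})

test_that("median smoothing removes spikes and preserves monotonicity", {
  flat <- pci_trace(1:21 / 10, c(rep(5, 10), 500, rep(5, 10)),
                    500, 10, "low_energy", "s")
  expect_equal(smooth_trace(flat, 5)$intensities, rep(5, 21))
  expect_identical(smooth_trace(flat, 1)$intensities, flat$intensities)
  mono <- pci_trace(1:30 / 10, cumsum(runif(30)), 500, 10, "low_energy", "s")
  sm <- smooth_trace(mono, 7)$intensities
  expect_true(!is.unsorted(sm))
  expect_error(smooth_trace(flat, 4), "odd")
})

test_that("profile ratio is exact for identities, scalings and masks", {
  run <- simulate_run(quick_scenario(), seed = 21)
  tg <- panel_targets(default_panel())[1, ]
  tr <- extract_xic(run, tg$mz, standard_id = tg$name)
  prof <- profile_ratio(tr, tr)
  expect_true(all(prof$ratio[!is.na(prof$ratio)] == 1))
  half <- tr; half$intensities <- 0.5 * tr$intensities
  expect_equal(unique(profile_ratio(half, tr)$ratio), 0.5)
  # reference below floor is masked, never infinite or zero-divided
  ref <- pci_trace(1:5, c(100, 100, 0, 0, 100), 500, 10, "low_energy", "s")
  sam <- pci_trace(1:5, rep(50, 5), 500, 10, "low_energy", "s")
  p <- profile_ratio(sam, ref, floor = 10)
  expect_true(all(is.na(p$ratio[3:4])))
  expect_equal(p$ratio[c(1, 2, 5)], rep(0.5, 3))
  late <- pci_trace(11:12, c(1, 1), 500, 10, "low_energy", "s")
  expect_error(profile_ratio(late, ref), "do not overlap")
})

test_that("region detection recovers box-event boundaries", {
  cfg <- quick_scenario("ppt_plasma", run_length = 5)
  run <- simulate_run(cfg, seed = 31)
  solv <- simulate_run(quick_scenario(run_length = 5), seed = 32)
  tg <- panel_targets(default_panel())[2, ]
  prof <- profile_ratio(extract_xic(run, tg$mz, standard_id = tg$name),
                        extract_xic(solv, tg$mz, standard_id = tg$name))
  regs <- detect_regions(prof)
  supp <- regs[regs$kind == "suppression", ]
  expect_equal(nrow(supp), 1L)
  scan_min <- cfg$scan_interval / 60
  expect_lt(abs(supp$start_min - 2.75), 2 * scan_min + 1e-9)
  expect_lt(abs(supp$end_min - 3.25), 2 * scan_min + 1e-9)
  expect_lt(supp$extreme_ratio, 0.3)
})

test_that("flat profiles yield no regions and thresholds are validated", {
  run <- simulate_run(quick_scenario(), seed = 33)
  tg <- panel_targets(default_panel())[1, ]
  tr <- extract_xic(run, tg$mz, standard_id = tg$name)
  prof <- profile_ratio(tr, tr)
  expect_equal(nrow(detect_regions(prof)), 0L)
  expect_error(detect_regions(prof, low = 1.2), "thresholds")
})

test_that("nearby same-kind dips merge across small gaps", {
  t <- seq(0, 1, by = 1 / 600)
  r <- rep(1, length(t))
  r[t >= 0.40 & t <= 0.46] <- 0.3
  r[t >= 0.48 & t <= 0.54] <- 0.3   # 0.02 min gap < merge_gap 0.03
  prof <- structure(list(times = t, sample = r, reference = rep(1, length(t)),
                         ratio = r, standard_id = "s", floor = 0),
                    class = "pci_profile")
  regs <- detect_regions(prof, smooth_window = 1L)
  expect_equal(nrow(regs), 1L)
  expect_equal(regs$start_min, 0.40, tolerance = 0.005)
  expect_equal(regs$end_min, 0.54, tolerance = 0.005)
  # masked points break intervals even across small gaps
  r2 <- r; r2[t > 0.465 & t < 0.475] <- NA
  prof$ratio <- r2
  regs2 <- detect_regions(prof, smooth_window = 1L, min_width = 0.04)
  expect_equal(nrow(regs2), 2L)
})

test_that("deepening an event never shrinks its detected region", {
  widths <- c()
  for (depth in c(0.5, 0.7, 0.9)) {
    cfg <- exact_scenario(run_length = 2)
    cfg$events <- list(suppression_event(1.0, 0.4, depth, shape = "gaussian"))
    run <- simulate_run(cfg, seed = 7)
    solv <- simulate_run(exact_scenario(run_length = 2), seed = 7)
    tg <- panel_targets(default_panel())[1, ]
    prof <- profile_ratio(extract_xic(run, tg$mz, standard_id = tg$name),
                          extract_xic(solv, tg$mz, standard_id = tg$name))
    regs <- detect_regions(prof)
    expect_equal(nrow(regs), 1L)
    widths <- c(widths, regs$end_min - regs$start_min)
  }
  expect_true(!is.unsorted(widths))
})

test_that("matrix effect percent follows the spike-comparison formula", {
  expect_equal(matrix_effect_percent(100, 100), 100)
  expect_equal(matrix_effect_percent(50, 100), 50)
  expect_error(matrix_effect_percent(10, 0), "> 0")
  # spiked response under a depth-0.4 event recovers ~60%
  cfg <- exact_scenario(run_length = 2)
  cfg$events <- list(suppression_event(1.0, 0.4, 0.4, shape = "box"))
  run <- simulate_run(cfg, seed = 8)
  solv <- simulate_run(exact_scenario(run_length = 2), seed = 8)
  tg <- panel_targets(default_panel())[4, ]
  at <- function(r) {
    tr <- extract_xic(r, tg$mz)
    tr$intensities[which.min(abs(tr$times - 1.0))]
  }
  expect_equal(matrix_effect_percent(at(run), at(solv)), 60, tolerance = 0.01)
})
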