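test_that("recovery law: zero at zero, 1 - 1/e at tau, saturates at the asymptote", {
  s <- subject_record("S1", "Control", 75,
                      group_params(tau_recovery_ms = 1000, amp_max_mm = 1.0))
  expect_identical(amplitude_law(0, s), 0)
  expect_equal(amplitude_law(1000, s), 1 - exp(-1), tolerance = 1e-12)
  expect_equal(amplitude_law(1e9, s), 1.0, tolerance = 1e-12)
  expect_error(amplitude_law(-1, s), "non-negative")
})

test_that("recovery law is monotone and age lowers the asymptote", {
  set.seed(11)
  for (i in 1:20) {
    s <- subject_record(
      "S", sample(c("AMD", "Control"), 1), runif(1, 55, 95),
      group_params(tau_recovery_ms = runif(1, 300, 5000),
                   amp_max_mm = runif(1, 0.3, 2))
    )
    d <- sort(runif(30, 0, 20000))
    a <- amplitude_law(d, s)
    expect_true(all(diff(a) >= 0))
    expect_true(all(a >= 0))
  }
  young <- subject_record("Y", "Control", 60, group_params())
  old <- subject_record("O", "Control", 90, group_params())
  expect_lt(amplitude_law(3000, old), amplitude_law(3000, young))
})

test_that("a slower time constant puts the AMD curve at or below control everywhere", {
  ctrl <- subject_record("C", "Control", 75,
                         group_params(tau_recovery_ms = 1200))
  amd <- subject_record("A", "AMD", 75,
                        group_params(tau_recovery_ms = 2400))
  d <- 100 * (1:50)
  expect_true(all(amplitude_law(d, amd) <= amplitude_law(d, ctrl)))
  expect_true(all(amplitude_law(d, amd)[-1] <
                    amplitude_law(d, ctrl)[-1]))
})

test_that("deterministic traces match the closed-form forward model in both ROIs", {
  p <- build_protocol()
  s <- subject_record("S1", "Control", 75, noise_free_params(), seed = 5)
  rec <- simulate_recording(s, p)
  ev <- reonset_times(p)
  dt <- 1000 / p$sample_rate_hz
  kp <- s$kernel_peak_ms
  for (i in c(1, 10, 25, 50)) {
    t_on <- ev$time_ms[i]
    a <- amplitude_law(ev$preceding_dark_ms[i], s)
    # direct evaluation of D_pre - A * g(t) on the sample grid
    grid_max <- seq(0, 100 - dt, by = dt)
    grid_min <- seq(100, 200 - dt, by = dt)
    g <- function(t) (t / kp) * exp(1 - t / kp)
    d_pre <- s$baseline_mm   # dark_gain 0: trace sits at baseline before re-onset
    expected_max <- max(d_pre - a * g(grid_max))
    expected_min <- min(d_pre - a * g(grid_min))
    got_max <- oracle_roi(rec, t_on, 0, 100, "max")
    got_min <- oracle_roi(rec, t_on, 100, 200, "min")
    expect_equal(got_max, expected_max, tolerance = 1e-6)
    expect_equal(got_min, expected_min, tolerance = 1e-6)
  }
})

test_that("trace simulation is reproducible and blink-free when configured so", {
  p <- build_protocol()
  s <- subject_record("S1", "AMD", 80,
                      group_params(blink_rate_hz = 0), seed = 9)
  r1 <- simulate_recording(s, p)
  r2 <- simulate_recording(s, p)
  expect_true(all(r1$samples$valid))
  expect_identical(r1$samples, r2$samples)

  s_blink <- subject_record("S2", "AMD", 80,
                            group_params(blink_rate_hz = 0.5), seed = 9)
  rb <- simulate_recording(s_blink, p)
  expect_gt(sum(!rb$samples$valid), 0)
  expect_true(all(is.na(rb$samples$diameter_mm[!rb$samples$valid])))
  expect_true(all(rb$samples$diameter_mm[rb$samples$valid] > 0))
})

test_that("a degenerate protocol is rejected by the simulator", {
  p1 <- toy_protocol("bright", 3000L)
  s <- subject_record("S1", "Control", 75, noise_free_params(), seed = 1)
  expect_error(simulate_recording(s, p1), "at least one")
})

test_that("cohorts have the configured size, shared ages and are seed-deterministic", {
  cfg <- cohort_config(seed = 21)
  co1 <- simulate_cohort_amplitudes(cfg)
  co2 <- simulate_cohort_amplitudes(cfg)
  expect_identical(nrow(co1$subjects), 28L)
  expect_identical(sum(co1$subjects$group == "AMD"), 14L)
  expect_identical(co1$subjects, co2$subjects)
  expect_identical(co1$table, co2$table)
  expect_identical(nrow(co1$table), 28L * 50L)

  ctrl_only <- simulate_cohort_amplitudes(cohort_config(n_amd = 0, seed = 3))
  expect_identical(unique(ctrl_only$subjects$group), "Control")
  expect_error(fit_lmm(ctrl_only$table), "two groups")
})

test_that("full-trace cohorts write bitwise-identical CSVs under one seed", {
  cfg <- cohort_config(n_amd = 1, n_control = 1, seed = 17)
  p <- build_protocol()
  f1 <- withr::local_tempfile(fileext = ".csv")
  f2 <- withr::local_tempfile(fileext = ".csv")
  write_recording(simulate_cohort(cfg, p)$recordings, f1)
  write_recording(simulate_cohort(cfg, p)$recordings, f2)
  expect_identical(unname(tools::md5sum(f1)), unname(tools::md5sum(f2)))
})

test_that("recording CSV round-trips, tolerates a missing valid column, rejects bad rows", {
  t_ms <- seq(0, 45, by = 5)
  d <- c(4, 4.1, NA, 4.2, 4.25, 4.3, NA, 4.1, 4.05, 4)
  valid <- !is.na(d)
  rec <- toy_recording(t_ms, d, valid)
  path <- withr::local_tempfile(fileext = ".csv")
  write_recording(rec, path)
  back <- read_recording(path)
  expect_s3_class(back, "plr_recording")
  expect_equal(back$samples$t_ms, rec$samples$t_ms)
  expect_equal(back$samples$diameter_mm, rec$samples$diameter_mm)
  expect_identical(back$samples$valid, rec$samples$valid)

  no_valid <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(data.frame(subject_id = "T1", eye = "left",
                              t_ms = t_ms, diameter_mm = seq(4, 4.9, 0.1)),
                   no_valid)
  expect_warning(r2 <- read_recording(no_valid), "valid")
  expect_true(all(r2$samples$valid))

  bad <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(data.frame(subject_id = "T1", eye = "left",
                              t_ms = c(0, 5, 5, 10), diameter_mm = 4,
                              valid = TRUE), bad)
  expect_error(read_recording(bad), "non-monotone t_ms.*row 3")
})
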