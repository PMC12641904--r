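ev1 <- function(t_on, dark = 100, cycle = 1L, phase = "ramp") {
  tibble::tibble(time_ms = t_on, preceding_dark_ms = dark,
                 cycle_id = cycle, phase = phase)
}

test_that("a constant trace has zero amplitude", {
  rec <- toy_recording(seq(0, 995, by = 5), rep(4, 200))
  row <- extract_cycle(rec, ev1(100))
  expect_identical(row$amplitude, 0)
  expect_identical(row$d_max_mm, 4)
  expect_false(row$missing)
})

test_that("extraction equals the closed-form trace oracle on a synthetic cycle", {
  p <- build_protocol()
  s <- subject_record("S1", "Control", 75,
                      noise_free_params(kernel_peak_ms = 150), seed = 2)
  rec <- simulate_recording(s, p)
  ev <- reonset_times(p)
  i <- which(ev$preceding_dark_ms == 1000)[1]
  a <- amplitude_law(1000, s)
  row <- extract_cycle(rec, ev[i, ])
  # kernel peaks at 150 ms, on the 5 ms grid, so the ROI minimum is exactly
  # baseline - A and the pre-constriction maximum is the baseline
  expect_equal(row$d_max_mm, s$baseline_mm, tolerance = 1e-6)
  expect_equal(row$d_min_mm, s$baseline_mm - a, tolerance = 1e-6)
  expect_equal(row$amplitude, a, tolerance = 1e-4)
})

test_that("an occluded ROI marks the cycle missing rather than imputing", {
  t_ms <- seq(0, 995, by = 5)
  d <- rep(4, 200)
  valid <- rep(TRUE, 200)
  t_on <- 500
  blink <- t_ms >= t_on + 100 & t_ms < t_on + 200
  valid[blink] <- FALSE
  d[blink] <- NA
  row <- extract_cycle(toy_recording(t_ms, d, valid), ev1(t_on))
  expect_true(row$missing)
  expect_identical(row$missing_reason, "roi_invalid")
  expect_true(is.na(row$amplitude))

  out <- extract_cycle(toy_recording(t_ms, rep(4, 200)), ev1(900))
  expect_identical(out$missing_reason, "out_of_span")
})

test_that("extraction equals an independent brute-force ROI scan on random traces", {
  set.seed(77)
  for (i in 1:25) {
    n <- 200
    t_ms <- seq(0, by = 5, length.out = n)
    d <- 4 + cumsum(rnorm(n, 0, 0.05))
    valid <- runif(n) > 0.1
    d[!valid] <- NA
    rec <- toy_recording(t_ms, d, valid)
    t_on <- sample(seq(0, 700, by = 5), 1)
    row <- extract_cycle(rec, ev1(t_on), roi_config(min_valid_fraction = 0))
    expect_identical(row$d_max_mm, oracle_roi(rec, t_on, 0, 100, "max"))
    expect_identical(row$d_min_mm, oracle_roi(rec, t_on, 100, 200, "min"))
    if (!row$missing) {
      expect_identical(row$amplitude, row$d_max_mm - row$d_min_mm)
    }
  }
})

test_that("ROI windows are half-open at 0, 100 and 200 ms", {
  t_ms <- seq(0, 995, by = 5)
  rec <- toy_recording(t_ms, t_ms / 100)  # strictly increasing trace
  row0 <- extract_cycle(rec, ev1(0))
  expect_identical(row0$d_max_mm, 95 / 100)    # t = 100 excluded from max ROI
  expect_identical(row0$d_min_mm, 100 / 100)   # t = 100 included in min ROI

  row5 <- extract_cycle(rec, ev1(5))           # shift re-onset by one sample
  expect_identical(row5$d_max_mm, 100 / 100)
  expect_identical(row5$d_min_mm, 105 / 100)   # t = 205 excluded from min ROI
})

test_that("a blink-free subject yields exactly 50 ramp rows, joined with identity", {
  p <- build_protocol()
  s <- subject_record("S1", "AMD", 81,
                      group_params(blink_rate_hz = 0), seed = 31)
  rec <- clean_recording(simulate_recording(s, p))
  tab <- build_amplitude_table(list(rec), p, s)
  ramp <- tab[tab$phase == "ramp", ]
  expect_identical(nrow(ramp), 50L)
  expect_true(all(!ramp$missing))
  expect_identical(sort(ramp$dark_ms), 100L * (1:50))
  expect_identical(unique(tab$group), "AMD")
  expect_identical(nrow(tab), nrow(reonset_times(p)))

  expect_identical(nrow(build_amplitude_table(list(), p, s)), 0L)
  stranger <- rec; stranger$subject_id <- "??"
  expect_error(build_amplitude_table(list(stranger), p, s),
               "not in the subject table")
})

test_that("eye averaging follows the available-case rule", {
  base <- tibble::tibble(
    subject_id = "S1", group = "AMD", age_years = 80, phase = "ramp",
    cycle_id = 1L, dark_ms = 100,
    d_max_mm = 4, d_min_mm = 3.6, missing = FALSE,
    missing_reason = NA_character_
  )
  two_eyes <- dplyr::bind_rows(
    dplyr::mutate(base, eye = "left", amplitude = 0.4),
    dplyr::mutate(base, eye = "right", amplitude = 0.6)
  )
  avg <- average_eyes(two_eyes)
  expect_identical(nrow(avg), 1L)
  expect_identical(avg$amplitude, 0.5)
  expect_identical(avg$eye, "both")

  one_missing <- two_eyes
  one_missing$missing[2] <- TRUE
  one_missing$amplitude[2] <- NA
  expect_identical(average_eyes(one_missing)$amplitude, 0.4)

  both_missing <- dplyr::mutate(two_eyes, missing = TRUE,
                                amplitude = NA_real_,
                                missing_reason = "roi_invalid")
  expect_true(average_eyes(both_missing)$missing)

  single <- dplyr::mutate(base, eye = "left", amplitude = 0.4)
  expect_identical(average_eyes(single), single)
})

test_that("recovery curves aggregate correctly and drop empty durations", {
  tab <- linear_form_table(n_per_group = 1, sigma = 0)
  one <- recovery_curve(tab, "Control")
  expect_identical(nrow(one), 50L)
  expect_true(all(one$sd_amplitude == 0))
  expect_equal(one$mean_amplitude,
               tab$amplitude[tab$group == "Control"][order(tab$dark_ms[tab$group == "Control"])],
               tolerance = 1e-12)

  tab2 <- tab
  tab2$missing[tab2$dark_ms == 300] <- TRUE
  curve2 <- recovery_curve(tab2)
  expect_false(300 %in% curve2$dark_ms)
  expect_error(recovery_curve(tab, "Elephants"), "unknown group")
})

test_that("noise-free recovery curves are non-decreasing for every subject", {
  p <- build_protocol()
  for (g in c("Control", "AMD")) {
    tau <- if (g == "AMD") 2400 else 1200
    s <- subject_record(paste0(g, "1"), g, 75,
                        noise_free_params(tau_recovery_ms = tau), seed = 4)
    rec <- clean_recording(simulate_recording(s, p))
    tab <- build_amplitude_table(list(rec), p, s)
    amp <- tab$amplitude[tab$phase == "ramp"][order(tab$dark_ms[tab$phase == "ramp"])]
    expect_true(all(diff(amp) > -1e-9))
  }
})

test_that("noise-free extraction recovers the programmed law within 1% at all 50 durations", {
  p <- build_protocol()
  s <- subject_record("S1", "AMD", 78,
                      noise_free_params(tau_recovery_ms = 2400), seed = 8)
  rec <- clean_recording(simulate_recording(s, p),
                         cleaning_config(smooth_window_ms = 0))
  tab <- build_amplitude_table(list(rec), p, s)
  ramp <- tab[tab$phase == "ramp", ]
  ramp <- ramp[order(ramp$dark_ms), ]
  truth <- amplitude_law(ramp$dark_ms, s)
  expect_true(all(abs(ramp$amplitude - truth) / truth < 0.01))
})
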