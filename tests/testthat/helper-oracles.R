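# Independent oracles and fixture builders shared across the test files.
# These deliberately re-derive quantities by brute force (loops, direct
# summation, closed forms) so the package implementation is checked against
# code that shares nothing with it.

# Total schedule length by direct summation of the narrated phases plus the
# closing bright epoch.
oracle_total_duration_ms <- function() {
  ramp <- 50 * 3000 + sum(100 * (1:50))
  tail_cycles <- (3000 + 7000) + (3000 + 10000) + (3000 + 15000)
  rep_block <- 10 * (3000 + 100)
  closing_bright <- 3000
  as.integer(ramp + tail_cycles + rep_block + closing_bright)
}

# Brute-force scan of an epoch list for dark -> bright transitions.
oracle_reonsets <- function(epochs) {
  out <- NULL
  for (i in seq_len(max(nrow(epochs) - 1, 0))) {
    if (epochs$level[i] == "dark" && epochs$level[i + 1] == "bright") {
      out <- rbind(out, data.frame(
        time_ms = epochs$onset_ms[i] + epochs$duration_ms[i],
        preceding_dark_ms = epochs$duration_ms[i],
        cycle_id = epochs$cycle_id[i],
        phase = epochs$phase[i]
      ))
    }
  }
  out
}

# Brute-force extremum over all samples of a recording falling in the
# half-open window [t_on + lo, t_on + hi).
oracle_roi <- function(rec, t_on, lo, hi, what = c("max", "min")) {
  what <- match.arg(what)
  best <- NA_real_
  s <- rec$samples
  for (i in seq_len(nrow(s))) {
    rel <- s$t_ms[i] - t_on
    if (rel >= lo && rel < hi && s$valid[i] && !is.na(s$diameter_mm[i])) {
      v <- s$diameter_mm[i]
      if (is.na(best) ||
          (what == "max" && v > best) ||
          (what == "min" && v < best)) {
        best <- v
      }
    }
  }
  best
}

toy_recording <- function(t_ms, diameter_mm,
                          valid = rep(TRUE, length(t_ms)),
                          subject_id = "T1", eye = "left",
                          sample_rate_hz = NULL) {
  if (is.null(sample_rate_hz)) {
    sample_rate_hz <- 1000 / stats::median(diff(t_ms))
  }
  structure(
    list(subject_id = subject_id, eye = eye,
         sample_rate_hz = sample_rate_hz, protocol_ref = "toy",
         samples = tibble::tibble(t_ms = t_ms, diameter_mm = diameter_mm,
                                  valid = valid)),
    class = "plr_recording"
  )
}

toy_protocol <- function(levels, durations,
                         phases = rep("ramp", length(levels)),
                         cycles = rep(1L, length(levels)),
                         sample_rate_hz = 200) {
  onset <- cumsum(c(0, durations[-length(durations)]))
  structure(
    list(epochs = tibble::tibble(
      index = seq_along(levels) - 1L, phase = phases, level = levels,
      onset_ms = as.integer(onset), duration_ms = as.integer(durations),
      cycle_id = as.integer(cycles)),
      bright_luminance_nits = 150, dark_luminance_nits = 0,
      sample_rate_hz = sample_rate_hz),
    class = "plr_protocol"
  )
}

# Parameters for deterministic traces whose measured amplitude equals the
# recovery law exactly (no noise, hippus, blinks or dark dilation drift).
noise_free_params <- function(...) {
  group_params(noise_sd_mm = 0, hippus_amp_mm = 0, blink_rate_hz = 0,
               dark_gain_mm = 0, ...)
}

# Amplitude table drawn from the mixed model's own linear form: iid
# Gaussian residuals around beta0 + beta_time * Time + beta_group * AMD.
linear_form_table <- function(n_per_group = 14, beta0 = 0.4,
                              beta_time = 1e-4, beta_group = 0,
                              sigma = 0.1, dark_ms = 100 * (1:50)) {
  n <- 2 * n_per_group
  subs <- data.frame(
    subject_id = sprintf("S%02d", seq_len(n)),
    group = rep(c("Control", "AMD"), each = n_per_group),
    age_years = round(stats::runif(n, 55, 90))
  )
  rows <- lapply(seq_len(n), function(i) {
    g <- as.numeric(subs$group[i] == "AMD")
    tibble::tibble(
      subject_id = subs$subject_id[i], eye = "left", group = subs$group[i],
      age_years = subs$age_years[i], phase = "ramp",
      cycle_id = seq_along(dark_ms), dark_ms = dark_ms,
      d_max_mm = NA_real_, d_min_mm = NA_real_,
      amplitude = beta0 + beta_time * dark_ms + beta_group * g +
        stats::rnorm(length(dark_ms), 0, sigma),
      missing = FALSE, missing_reason = NA_character_
    )
  })
  dplyr::bind_rows(rows)
}

# A cohort whose groups are separated far beyond the within-group spread:
# a mean-amplitude threshold alone would classify it perfectly.
separable_config <- function(seed = 1L) {
  cohort_config(
    seed = seed, jitter_sdlog = 0.05,
    group_params = list(
      Control = group_params(amp_max_mm = 1.0, amp_noise_sd_mm = 0.01),
      AMD = group_params(amp_max_mm = 0.5, tau_recovery_ms = 2400,
                         amp_noise_sd_mm = 0.01)
    )
  )
}
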