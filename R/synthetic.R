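#' Group-level generative parameters
#'
#' Parameters of the forward model that generates synthetic pupil recordings
#' for one group. Recovery of the constriction amplitude in darkness follows
#' a saturating exponential with time constant `tau_recovery_ms`; a slower
#' (larger) time constant produces the slowed dark adaptation that
#' characterises macular degeneration. The asymptotic amplitude declines
#' linearly with age at `age_slope_mm_per_year`, with a smaller slope in the
#' AMD group realising an age-by-group interaction.
#'
#' @param tau_recovery_ms Saturating-exponential time constant of amplitude
#'   recovery in darkness (ms).
#' @param amp_max_mm Asymptotic constriction amplitude at the reference age
#'   (mm).
#' @param age_slope_mm_per_year Linear decline of the asymptotic amplitude
#'   per year of age (mm/year).
#' @param baseline_mm Bright-adapted pupil diameter (mm).
#' @param dark_gain_mm Asymptotic extra dilation in darkness (mm).
#' @param tau_dilation_ms Dilation/re-constriction relaxation time constant
#'   (ms).
#' @param kernel_peak_ms Time-to-peak of the constriction kernel after light
#'   re-onset (ms); the default 150 ms places the trace minimum inside the
#'   100-200 ms region of interest.
#' @param noise_sd_mm White measurement noise SD per sample (mm).
#' @param hippus_amp_mm,hippus_freq_hz Amplitude (mm) and frequency (Hz) of
#'   the slow pupil-unrest sinusoid.
#' @param blink_rate_hz Poisson rate of blink gaps (events per second).
#' @param blink_dur_ms_range Length-2 numeric, min/max blink gap length (ms).
#' @param amp_noise_sd_mm Cycle-level amplitude noise SD (mm) used by the
#'   table-level generator [simulate_cohort_amplitudes()].
#' @return A `plr_group_params` list.
#' @seealso [default_group_params()] for the two-group defaults.
#' @export
group_params <- function(tau_recovery_ms = 1200,
                         amp_max_mm = 1.0,
                         age_slope_mm_per_year = 0.008,
                         baseline_mm = 4.0,
                         dark_gain_mm = 2.0,
                         tau_dilation_ms = 800,
                         kernel_peak_ms = 150,
                         noise_sd_mm = 0.03,
                         hippus_amp_mm = 0.10,
                         hippus_freq_hz = 0.2,
                         blink_rate_hz = 0.2,
                         blink_dur_ms_range = c(100, 300),
                         amp_noise_sd_mm = 0.05) {
  stopifnot(
    tau_recovery_ms > 0, amp_max_mm > 0, baseline_mm > 0,
    kernel_peak_ms > 0, tau_dilation_ms > 0,
    noise_sd_mm >= 0, hippus_amp_mm >= 0, blink_rate_hz >= 0,
    amp_noise_sd_mm >= 0, dark_gain_mm >= 0,
    length(blink_dur_ms_range) == 2, all(blink_dur_ms_range > 0)
  )
  structure(
    list(
      tau_recovery_ms = tau_recovery_ms,
      amp_max_mm = amp_max_mm,
      age_slope_mm_per_year = age_slope_mm_per_year,
      baseline_mm = baseline_mm,
      dark_gain_mm = dark_gain_mm,
      tau_dilation_ms = tau_dilation_ms,
      kernel_peak_ms = kernel_peak_ms,
      noise_sd_mm = noise_sd_mm,
      hippus_amp_mm = hippus_amp_mm,
      hippus_freq_hz = hippus_freq_hz,
      blink_rate_hz = blink_rate_hz,
      blink_dur_ms_range = blink_dur_ms_range,
      amp_noise_sd_mm = amp_noise_sd_mm
    ),
    class = "plr_group_params"
  )
}

#' Default two-group generative parameters
#'
#' The AMD group recovers with twice the control time constant (slower dark
#' adaptation) and shows a weaker age-related amplitude decline, so that the
#' age effect is attenuated in AMD relative to controls.
#'
#' @return Named list with `Control` and `AMD` [group_params()].
#' @export
default_group_params <- function() {
  list(
    Control = group_params(),
    AMD = group_params(tau_recovery_ms = 2400, age_slope_mm_per_year = 0.003)
  )
}

#' Cohort-level simulation configuration
#'
#' @param n_amd,n_control Group sizes (default 14 + 14). `0` is allowed to
#'   create degenerate one-group cohorts; downstream group contrasts then
#'   fail loudly.
#' @param age_mean_years,age_sd_years Shared (age-matched) age distribution.
#' @param age_reference_years Age at which `amp_max_mm` applies.
#' @param jitter_sdlog Log-SD of the per-subject lognormal perturbation of
#'   `tau_recovery_ms`, `amp_max_mm`, `baseline_mm` and `dark_gain_mm`
#'   (between-subject variability; 0 disables).
#' @param seed Integer RNG seed for the cohort draw.
#' @param group_params Named list of [group_params()] per group label.
#' @return A `plr_cohort_config` list.
#' @export
cohort_config <- function(n_amd = 14,
                          n_control = 14,
                          age_mean_years = 75,
                          age_sd_years = 7,
                          age_reference_years = 75,
                          jitter_sdlog = 0.1,
                          seed = 1L,
                          group_params = default_group_params()) {
  stopifnot(
    n_amd >= 0, n_control >= 0, n_amd + n_control >= 1,
    age_sd_years >= 0, jitter_sdlog >= 0,
    all(c("Control", "AMD") %in% names(group_params) |
          c(n_control, n_amd) == 0)
  )
  structure(
    list(
      n_amd = as.integer(n_amd), n_control = as.integer(n_control),
      age_mean_years = age_mean_years, age_sd_years = age_sd_years,
      age_reference_years = age_reference_years,
      jitter_sdlog = jitter_sdlog,
      seed = as.integer(seed),
      group_params = group_params
    ),
    class = "plr_cohort_config"
  )
}

#' Construct a single subject record
#'
#' A subject record carries the realised (per-subject) generative parameters
#' together with identity, group, age and seed. [simulate_cohort()] creates
#' these with between-subject jitter; this constructor is the deterministic
#' path (parameters taken as given), convenient for targeted simulations.
#'
#' @param subject_id Identifier string.
#' @param group `"AMD"` or `"Control"`.
#' @param age_years Age, must be positive.
#' @param params A [group_params()] object (used as the realised values).
#' @param seed Per-subject RNG seed for trace simulation.
#' @param age_reference_years Reference age for the amplitude asymptote.
#' @return One-row tibble with identity columns and realised parameters.
#' @export
subject_record <- function(subject_id, group, age_years,
                           params = group_params(), seed = 1L,
                           age_reference_years = 75) {
  stopifnot(group %in% c("AMD", "Control"), age_years > 0)
  tibble(
    subject_id = subject_id,
    group = group,
    age_years = age_years,
    seed = as.integer(seed),
    age_reference_years = age_reference_years,
    tau_recovery_ms = params$tau_recovery_ms,
    amp_max_mm = params$amp_max_mm,
    age_slope_mm_per_year = params$age_slope_mm_per_year,
    baseline_mm = params$baseline_mm,
    dark_gain_mm = params$dark_gain_mm,
    tau_dilation_ms = params$tau_dilation_ms,
    kernel_peak_ms = params$kernel_peak_ms,
    noise_sd_mm = params$noise_sd_mm,
    hippus_amp_mm = params$hippus_amp_mm,
    hippus_freq_hz = params$hippus_freq_hz,
    blink_rate_hz = params$blink_rate_hz,
    blink_dur_min_ms = params$blink_dur_ms_range[1],
    blink_dur_max_ms = params$blink_dur_ms_range[2],
    amp_noise_sd_mm = params$amp_noise_sd_mm
  )
}

#' Dark-adaptation recovery law
#'
#' Constriction amplitude available after `dark_ms` of darkness:
#' `A(d) = A_inf * (1 - exp(-d / tau))`, where the asymptote
#' `A_inf = amp_max_mm - age_slope_mm_per_year * (age - age_reference)`
#' declines linearly with age and is floored at zero. The law is monotone
#' non-decreasing in `d`, zero at `d = 0`, and saturates at `A_inf`.
#'
#' @param dark_ms Non-negative dark duration(s) in ms.
#' @param subject A subject record (one row; see [subject_record()]).
#' @return Amplitude(s) in mm.
#' @export
amplitude_law <- function(dark_ms, subject) {
  if (any(dark_ms < 0)) stop("dark_ms must be non-negative")
  a_inf <- max(
    0,
    subject$amp_max_mm -
      subject$age_slope_mm_per_year *
        (subject$age_years - subject$age_reference_years)
  )
  pmax(0, a_inf * (1 - exp(-dark_ms / subject$tau_recovery_ms)))
}

# Unimodal constriction kernel: g(0) = 0, g(peak) = 1, decays afterwards.
constriction_kernel <- function(t_ms, kernel_peak_ms) {
  ifelse(t_ms < 0, 0,
         (t_ms / kernel_peak_ms) * exp(1 - t_ms / kernel_peak_ms))
}

#' Simulate one pupil recording under a protocol
#'
#' Forward model of a uniformly sampled pupil-diameter trace. In dark epochs
#' the diameter relaxes from its value at dark onset toward
#' `baseline_mm + dark_gain_mm` with time constant `tau_dilation_ms`. At each
#' light re-onset the trace follows
#' `baseline + (D_pre - baseline) * exp(-t / tau_dilation) - A(d) * g(t)`,
#' where `D_pre` is the diameter at re-onset, `d` the preceding dark
#' duration, `A` the recovery law ([amplitude_law()]) and
#' `g(t) = (t / peak) * exp(1 - t / peak)` the unimodal constriction kernel,
#' so the trace returns to baseline before the next dark onset. A hippus
#' sinusoid (random phase) and white noise are added; blink gaps occur at
#' Poisson times, with affected samples flagged invalid and their diameter
#' set to `NA`.
#'
#' @param subject One-row subject record ([subject_record()]).
#' @param protocol A `plr_protocol`.
#' @param seed RNG seed (default: the subject's own seed). Identical
#'   subject/protocol/seed give bitwise-identical recordings.
#' @param eye `"left"` or `"right"`.
#' @return A `plr_recording`: list with `subject_id`, `eye`,
#'   `sample_rate_hz`, `protocol_ref` and a `samples` tibble
#'   (`t_ms`, `diameter_mm`, `valid`).
#' @export
simulate_recording <- function(subject, protocol, seed = subject$seed,
                               eye = "left") {
  stopifnot(inherits(protocol, "plr_protocol"))
  if (nrow(protocol$epochs) < 2) {
    stop("protocol must contain at least one bright/dark cycle")
  }
  sr <- protocol$sample_rate_hz
  dt <- 1000 / sr
  total <- protocol_duration_ms(protocol)
  n <- floor(total / dt)
  t_ms <- seq(0, by = dt, length.out = n)

  base <- subject$baseline_mm
  tau_dil <- subject$tau_dilation_ms
  d <- numeric(n)
  d_cur <- base
  e <- protocol$epochs
  prev_dark <- NA_real_
  for (i in seq_len(nrow(e))) {
    idx0 <- e$onset_ms[i] / dt
    idx <- seq.int(idx0 + 1, length.out = e$duration_ms[i] / dt)
    tr <- t_ms[idx] - e$onset_ms[i]
    if (e$level[i] == "dark") {
      target <- base + subject$dark_gain_mm
      d[idx] <- target + (d_cur - target) * exp(-tr / tau_dil)
      d_cur <- target + (d_cur - target) * exp(-e$duration_ms[i] / tau_dil)
      prev_dark <- e$duration_ms[i]
    } else {
      relax <- (d_cur - base) * exp(-tr / tau_dil)
      if (is.na(prev_dark)) {
        d[idx] <- base + relax
      } else {
        amp <- amplitude_law(prev_dark, subject)
        d[idx] <- base + relax -
          amp * constriction_kernel(tr, subject$kernel_peak_ms)
      }
      d_end <- (d_cur - base) * exp(-e$duration_ms[i] / tau_dil)
      if (!is.na(prev_dark)) {
        d_end <- d_end - amplitude_law(prev_dark, subject) *
          constriction_kernel(e$duration_ms[i], subject$kernel_peak_ms)
      }
      d_cur <- base + d_end
    }
  }

  valid <- rep(TRUE, n)
  with_local_seed(seed, {
    if (subject$hippus_amp_mm > 0) {
      phase <- runif(1, 0, 2 * pi)
      d <- d + subject$hippus_amp_mm *
        sin(2 * pi * subject$hippus_freq_hz * t_ms / 1000 + phase)
    }
    if (subject$noise_sd_mm > 0) {
      d <- d + rnorm(n, 0, subject$noise_sd_mm)
    }
    if (subject$blink_rate_hz > 0) {
      n_blinks <- rpois(1, subject$blink_rate_hz * total / 1000)
      if (n_blinks > 0) {
        starts <- runif(n_blinks, 0, total)
        durs <- runif(n_blinks, subject$blink_dur_min_ms,
                      subject$blink_dur_max_ms)
        for (b in seq_len(n_blinks)) {
          valid[t_ms >= starts[b] & t_ms < starts[b] + durs[b]] <- FALSE
        }
      }
    }
  })
  d[!valid] <- NA_real_

  structure(
    list(
      subject_id = subject$subject_id,
      eye = eye,
      sample_rate_hz = sr,
      protocol_ref = sprintf("plr-protocol-%de-%dms", nrow(e), total),
      samples = tibble(t_ms = t_ms, diameter_mm = d, valid = valid)
    ),
    class = "plr_recording"
  )
}

#' @export
print.plr_recording <- function(x, ...) {
  cat("<plr_recording>", x$subject_id, "/", x$eye, "\n")
  cat(sprintf("  %d samples at %g Hz (%.1f s), %d invalid\n",
              nrow(x$samples), x$sample_rate_hz,
              nrow(x$samples) / x$sample_rate_hz, sum(!x$samples$valid)))
  invisible(x)
}

# Draw per-subject realised parameters for one group (lognormal jitter on
# the scale-type parameters; noise/hippus/blink parameters are shared).
realize_subjects <- function(n, group, config) {
  if (n == 0) return(NULL)
  gp <- config$group_params[[group]]
  rows <- lapply(seq_len(n), function(i) {
    jit <- function(x) x * rlnorm(1, 0, config$jitter_sdlog)
    p <- gp
    p$tau_recovery_ms <- jit(gp$tau_recovery_ms)
    p$amp_max_mm <- jit(gp$amp_max_mm)
    p$baseline_mm <- jit(gp$baseline_mm)
    p$dark_gain_mm <- jit(gp$dark_gain_mm)
    subject_record(
      subject_id = sprintf("%s%02d", ifelse(group == "AMD", "A", "C"), i),
      group = group,
      age_years = max(1, rnorm(1, config$age_mean_years, config$age_sd_years)),
      params = p,
      seed = sample.int(.Machine$integer.max - 1L, 1),
      age_reference_years = config$age_reference_years
    )
  })
  dplyr::bind_rows(rows)
}

#' Simulate a full cohort of pupil recordings
#'
#' Draws `n_amd + n_control` subjects with ages from the shared (age-matched)
#' distribution and per-subject lognormal parameter jitter, then simulates
#' one recording per subject (one eye, left) under the protocol. Fully
#' deterministic under `config$seed`.
#'
#' @param config A [cohort_config()].
#' @param protocol A `plr_protocol` (default [build_protocol()]).
#' @return List with `subjects` (tibble of subject records) and `recordings`
#'   (list of `plr_recording`).
#' @export
simulate_cohort <- function(config, protocol = build_protocol()) {
  stopifnot(inherits(config, "plr_cohort_config"))
  subjects <- with_local_seed(config$seed, {
    dplyr::bind_rows(
      realize_subjects(config$n_amd, "AMD", config),
      realize_subjects(config$n_control, "Control", config)
    )
  })
  recordings <- lapply(seq_len(nrow(subjects)), function(i) {
    simulate_recording(subjects[i, ], protocol)
  })
  list(subjects = subjects, recordings = recordings)
}

#' Simulate cycle-wise amplitudes directly from the recovery law
#'
#' The table-level counterpart of [simulate_cohort()]: instead of
#' synthesising and re-measuring full 200 Hz traces, it draws each subject's
#' ramp-cycle amplitudes directly as
#' `amplitude_law(dark_ms) + N(0, amp_noise_sd_mm)`. This is the generator
#' used for large replication studies (mixed-model calibration and power),
#' where trace synthesis would only add the extraction layer already
#' validated elsewhere.
#'
#' @param config A [cohort_config()].
#' @param dark_ms Ramp dark durations (default `100 * 1:50` ms).
#' @return List with `subjects` and `table` (an amplitude table with columns
#'   `subject_id`, `eye`, `group`, `age_years`, `phase`, `cycle_id`,
#'   `dark_ms`, `d_max_mm`, `d_min_mm`, `amplitude`, `missing`,
#'   `missing_reason`).
#' @export
simulate_cohort_amplitudes <- function(config,
                                       dark_ms = 100 * seq_len(50)) {
  stopifnot(inherits(config, "plr_cohort_config"))
  with_local_seed(config$seed, {
    subjects <- dplyr::bind_rows(
      realize_subjects(config$n_amd, "AMD", config),
      realize_subjects(config$n_control, "Control", config)
    )
    tabs <- lapply(seq_len(nrow(subjects)), function(i) {
      s <- subjects[i, ]
      amp <- amplitude_law(dark_ms, s) +
        rnorm(length(dark_ms), 0, s$amp_noise_sd_mm)
      tibble(
        subject_id = s$subject_id, eye = "left", group = s$group,
        age_years = s$age_years, phase = "ramp",
        cycle_id = seq_along(dark_ms), dark_ms = dark_ms,
        d_max_mm = NA_real_, d_min_mm = NA_real_,
        amplitude = amp, missing = FALSE,
        missing_reason = NA_character_
      )
    })
    list(subjects = subjects, table = dplyr::bind_rows(tabs))
  })
}
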