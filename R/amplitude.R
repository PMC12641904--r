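#' Region-of-interest configuration for amplitude extraction
#'
#' The constriction amplitude of a cycle is the maximum pupil diameter in a
#' window just after light re-onset minus the minimum diameter in the window
#' where the constriction trough falls. Windows are half-open intervals in
#' milliseconds relative to re-onset, so the two default windows partition
#' the first 200 ms without double-counting the boundary sample.
#'
#' @param max_window_ms Half-open interval for the pre-constriction maximum
#'   (default `c(0, 100)`).
#' @param min_window_ms Half-open interval for the constriction minimum
#'   (default `c(100, 200)`).
#' @param min_valid_fraction Minimum fraction of valid samples required in
#'   each window (default 0.8); below it the cycle is marked missing.
#' @return A `plr_roi_config` list.
#' @export
roi_config <- function(max_window_ms = c(0, 100),
                       min_window_ms = c(100, 200),
                       min_valid_fraction = 0.8) {
  stopifnot(
    length(max_window_ms) == 2, length(min_window_ms) == 2,
    max_window_ms[2] > max_window_ms[1],
    min_window_ms[2] > min_window_ms[1],
    max_window_ms[2] <= min_window_ms[1],
    min_valid_fraction >= 0, min_valid_fraction <= 1
  )
  structure(
    list(max_window_ms = max_window_ms, min_window_ms = min_window_ms,
         min_valid_fraction = min_valid_fraction),
    class = "plr_roi_config"
  )
}

roi_stat <- function(samples, t_on, window, fun) {
  rel <- samples$t_ms - t_on
  in_win <- rel >= window[1] & rel < window[2]
  n_win <- sum(in_win)
  ok <- in_win & samples$valid & !is.na(samples$diameter_mm)
  list(
    value = if (any(ok)) fun(samples$diameter_mm[ok]) else NA_real_,
    n_window = n_win,
    frac_valid = if (n_win > 0) sum(ok) / n_win else 0
  )
}

#' Extract the amplitude of one cycle
#'
#' `d_max` is the maximum valid diameter with `t - t_reonset` in the max
#' window, `d_min` the minimum valid diameter in the min window, and the
#' amplitude their difference. Negative amplitudes on noisy traces are
#' preserved (clipping would bias group means). The row is marked missing
#' with reason `"roi_invalid"` when either window has fewer valid samples
#' than `min_valid_fraction` requires, and `"out_of_span"` when the windows
#' fall outside the recording.
#'
#' @param rec A cleaned `plr_recording`.
#' @param reonset One row of [reonset_times()] (fields `time_ms`,
#'   `preceding_dark_ms`, `cycle_id`, `phase`).
#' @param roi A [roi_config()].
#' @return One-row amplitude tibble (`subject_id`, `eye`, `phase`,
#'   `cycle_id`, `dark_ms`, `d_max_mm`, `d_min_mm`, `amplitude`, `missing`,
#'   `missing_reason`).
#' @export
extract_cycle <- function(rec, reonset, roi = roi_config()) {
  t_on <- reonset$time_ms
  s <- rec$samples
  span_ok <- t_on >= s$t_ms[1] &&
    (t_on + roi$min_window_ms[2]) <= (s$t_ms[nrow(s)] + 1000 / rec$sample_rate_hz)
  if (!span_ok) {
    return(tibble(
      subject_id = rec$subject_id, eye = rec$eye,
      phase = reonset$phase, cycle_id = reonset$cycle_id,
      dark_ms = reonset$preceding_dark_ms,
      d_max_mm = NA_real_, d_min_mm = NA_real_, amplitude = NA_real_,
      missing = TRUE, missing_reason = "out_of_span"
    ))
  }
  mx <- roi_stat(s, t_on, roi$max_window_ms, max)
  mn <- roi_stat(s, t_on, roi$min_window_ms, min)
  bad <- mx$frac_valid < roi$min_valid_fraction ||
    mn$frac_valid < roi$min_valid_fraction
  tibble(
    subject_id = rec$subject_id, eye = rec$eye,
    phase = reonset$phase, cycle_id = reonset$cycle_id,
    dark_ms = reonset$preceding_dark_ms,
    d_max_mm = if (bad) NA_real_ else mx$value,
    d_min_mm = if (bad) NA_real_ else mn$value,
    amplitude = if (bad) NA_real_ else mx$value - mn$value,
    missing = bad,
    missing_reason = if (bad) "roi_invalid" else NA_character_
  )
}

#' Build the cycle-wise amplitude table for a set of recordings
#'
#' Runs [extract_cycle()] at every light re-onset of the protocol for every
#' recording and joins subject group and age. Ramp rows carry
#' `dark_ms = 100 * k`; tail and repeat rows are labeled by phase (they are
#' extracted and reported but excluded from the default model input by
#' [fit_lmm()]).
#'
#' @param recordings List of cleaned `plr_recording`s.
#' @param protocol The shared `plr_protocol`.
#' @param subjects Subject tibble (must contain `subject_id`, `group`,
#'   `age_years` for every recorded subject).
#' @param roi A [roi_config()].
#' @return Amplitude table tibble; empty input gives an empty table.
#' @export
build_amplitude_table <- function(recordings, protocol, subjects,
                                  roi = roi_config()) {
  events <- reonset_times(protocol)
  tabs <- lapply(recordings, function(rec) {
    if (!rec$subject_id %in% subjects$subject_id) {
      stop("recording subject '", rec$subject_id,
           "' is not in the subject table")
    }
    rows <- lapply(seq_len(nrow(events)), function(i) {
      extract_cycle(rec, events[i, ], roi)
    })
    dplyr::bind_rows(rows)
  })
  tab <- dplyr::bind_rows(tabs)
  if (nrow(tab) == 0) {
    return(tibble(
      subject_id = character(), eye = character(), group = character(),
      age_years = numeric(), phase = character(), cycle_id = integer(),
      dark_ms = numeric(), d_max_mm = numeric(), d_min_mm = numeric(),
      amplitude = numeric(), missing = logical(),
      missing_reason = character()
    ))
  }
  tab |>
    dplyr::left_join(
      subjects[, c("subject_id", "group", "age_years")],
      by = "subject_id"
    ) |>
    dplyr::relocate("group", "age_years", .after = "eye")
}

#' Average amplitudes across eyes
#'
#' For every subject and cycle, the amplitude is the mean of the non-missing
#' per-eye amplitudes (available-case rule: one missing eye falls back to
#' the other). Single-eye tables pass through unchanged; cycles missing in
#' all eyes stay missing.
#'
#' @param table Amplitude table.
#' @return Amplitude table with one row per subject and cycle (`eye` set to
#'   `"both"` where two eyes were combined).
#' @export
average_eyes <- function(table) {
  if (length(unique(table$eye)) <= 1) return(table)
  table |>
    dplyr::group_by(.data$subject_id, .data$group, .data$age_years,
                    .data$phase, .data$cycle_id, .data$dark_ms) |>
    dplyr::summarise(
      eye = if (dplyr::n() > 1) "both" else .data$eye[1],
      d_max_mm = if (all(.data$missing)) NA_real_ else
        mean(.data$d_max_mm[!.data$missing]),
      d_min_mm = if (all(.data$missing)) NA_real_ else
        mean(.data$d_min_mm[!.data$missing]),
      amplitude = if (all(.data$missing)) NA_real_ else
        mean(.data$amplitude[!.data$missing]),
      missing = all(.data$missing),
      missing_reason = if (all(.data$missing)) .data$missing_reason[1] else
        NA_character_,
      .groups = "drop"
    ) |>
    dplyr::relocate("eye", .after = "subject_id") |>
    dplyr::arrange(.data$subject_id, .data$cycle_id)
}

#' Cross-subject recovery curve
#'
#' Mean and SD of the ramp-cycle amplitude at each dark duration across the
#' subjects of one group (or all subjects). Missing rows are excluded; a
#' dark duration missing in every subject is omitted from the curve.
#'
#' @param table Amplitude table.
#' @param group Optional group label to filter on; an unknown label errors.
#' @return Tibble with `dark_ms`, `mean_amplitude`, `sd_amplitude`,
#'   `n_subjects`.
#' @export
recovery_curve <- function(table, group = NULL) {
  if (!is.null(group)) {
    if (!group %in% table$group) stop("unknown group label: ", group)
    table <- table[table$group == group, ]
  }
  table |>
    dplyr::filter(.data$phase == "ramp", !.data$missing) |>
    dplyr::group_by(.data$dark_ms) |>
    dplyr::summarise(
      mean_amplitude = mean(.data$amplitude),
      sd_amplitude = if (dplyr::n() > 1) sd(.data$amplitude) else 0,
      n_subjects = dplyr::n(),
      .groups = "drop"
    ) |>
    dplyr::arrange(.data$dark_ms)
}
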