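#' Cleaning configuration
#'
#' Defaults are deliberately conservative: only physiologically impossible
#' velocities are rejected, only short gaps are bridged, and smoothing uses a
#' 25 ms window (5 samples at 200 Hz).
#'
#' @param max_interp_gap_ms Longest invalid gap to interpolate linearly (ms).
#' @param velocity_limit_mm_per_s Absolute sample-to-sample velocity above
#'   which samples are rejected as artifacts (mm/s).
#' @param smooth_window_ms Centered moving-average window (ms); 0 disables
#'   smoothing.
#' @return A `plr_cleaning_config` list.
#' @export
cleaning_config <- function(max_interp_gap_ms = 300,
                            velocity_limit_mm_per_s = 50,
                            smooth_window_ms = 25) {
  stopifnot(max_interp_gap_ms >= 0, velocity_limit_mm_per_s >= 0,
            smooth_window_ms >= 0)
  structure(
    list(
      max_interp_gap_ms = max_interp_gap_ms,
      velocity_limit_mm_per_s = velocity_limit_mm_per_s,
      smooth_window_ms = smooth_window_ms
    ),
    class = "plr_cleaning_config"
  )
}

# invalid runs as a data.frame of start/end indices
invalid_runs <- function(valid) {
  r <- rle(!valid)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  data.frame(start = starts[r$values], end = ends[r$values])
}

#' Flag velocity artifacts
#'
#' Marks invalid every sample whose backward first-difference velocity
#' exceeds the limit (both endpoints of an exceeding difference are rejected,
#' since the step does not identify which of the two samples is wrong), then
#' widens every run containing newly rejected samples by one sample on each
#' side. Differences involving already-invalid samples are `NA` and never
#' flag, which makes the operation idempotent.
#'
#' @param rec A `plr_recording`.
#' @param cfg A [cleaning_config()].
#' @return The recording with updated `valid` flags (`diameter_mm` of newly
#'   invalid samples set to `NA`).
#' @export
flag_artifacts <- function(rec, cfg = cleaning_config()) {
  s <- rec$samples
  n <- nrow(s)
  dt_s <- 1 / rec$sample_rate_hz
  v <- c(NA, diff(s$diameter_mm)) / dt_s
  exceed <- !is.na(v) & abs(v) > cfg$velocity_limit_mm_per_s
  new_bad <- exceed | c(exceed[-1], FALSE)   # both endpoints of a bad diff
  flagged <- !s$valid | new_bad
  if (any(new_bad)) {
    runs <- invalid_runs(!flagged)  # runs of flagged samples
    # widen only runs that contain a newly rejected sample
    keep <- vapply(seq_len(nrow(runs)), function(i) {
      any(new_bad[runs$start[i]:runs$end[i]])
    }, logical(1))
    for (i in which(keep)) {
      lo <- max(1, runs$start[i] - 1)
      hi <- min(n, runs$end[i] + 1)
      flagged[lo:hi] <- TRUE
    }
  }
  s$valid <- !flagged
  s$diameter_mm[flagged] <- NA_real_
  rec$samples <- s
  rec
}

#' Interpolate short invalid gaps
#'
#' Gaps no longer than `max_interp_gap_ms` that are bounded by valid samples
#' on both sides are filled by linear interpolation between the boundary
#' samples and marked valid (and `interpolated`). Longer gaps and gaps at the
#' recording edges are left untouched (no extrapolation).
#'
#' @param rec A `plr_recording` (artifacts already flagged).
#' @param cfg A [cleaning_config()].
#' @return The recording with interpolated samples; the samples tibble gains
#'   an `interpolated` logical column (in-memory only, not part of the CSV
#'   dialect).
#' @export
interpolate_gaps <- function(rec, cfg = cleaning_config()) {
  s <- rec$samples
  n <- nrow(s)
  if (!"interpolated" %in% names(s)) s$interpolated <- FALSE
  dt <- 1000 / rec$sample_rate_hz
  runs <- invalid_runs(s$valid)
  if (nrow(runs)) {
    for (i in seq_len(nrow(runs))) {
      a <- runs$start[i]; b <- runs$end[i]
      if (a == 1 || b == n) next                      # edge gap: never extrapolate
      if ((b - a + 1) * dt > cfg$max_interp_gap_ms) next
      lo <- a - 1; hi <- b + 1
      if (!s$valid[lo] || !s$valid[hi]) next
      fill <- approx(
        x = s$t_ms[c(lo, hi)], y = s$diameter_mm[c(lo, hi)],
        xout = s$t_ms[a:b]
      )$y
      s$diameter_mm[a:b] <- fill
      s$valid[a:b] <- TRUE
      s$interpolated[a:b] <- TRUE
    }
  }
  rec$samples <- s
  rec
}

#' Smooth a recording with a centered moving average
#'
#' Each valid sample is replaced by the mean of the valid samples within the
#' centered window (truncated at the recording edges); invalid samples stay
#' invalid. `smooth_window_ms = 0` is the identity.
#'
#' @param rec A `plr_recording` (gaps handled).
#' @param cfg A [cleaning_config()].
#' @return The smoothed recording.
#' @export
smooth_recording <- function(rec, cfg = cleaning_config()) {
  if (cfg$smooth_window_ms == 0) return(rec)
  s <- rec$samples
  dt <- 1000 / rec$sample_rate_hz
  w <- max(1, round(cfg$smooth_window_ms / dt))
  if (w %% 2 == 0) w <- w + 1
  h <- (w - 1) / 2
  n <- nrow(s)
  val <- ifelse(s$valid, s$diameter_mm, 0)
  cnt <- as.numeric(s$valid)
  cs_v <- cumsum(val)
  cs_c <- cumsum(cnt)
  lo <- pmax(seq_len(n) - h, 1)
  hi <- pmin(seq_len(n) + h, n)
  num <- cs_v[hi] - c(0, cs_v)[lo]
  den <- cs_c[hi] - c(0, cs_c)[lo]
  sm <- ifelse(den > 0, num / den, NA_real_)
  s$diameter_mm <- ifelse(s$valid, sm, s$diameter_mm)
  rec$samples <- s
  rec
}

#' Full cleaning pipeline
#'
#' Applies [flag_artifacts()], [interpolate_gaps()] and [smooth_recording()]
#' in that order and marks the recording as cleaned. Cleaning a recording
#' twice is the identity on the second pass (the `cleaned` marker prevents
#' re-smoothing).
#'
#' @param rec A `plr_recording`.
#' @param cfg A [cleaning_config()].
#' @return The cleaned recording (attribute `cleaned = TRUE`), with a
#'   `cleaning_report` attribute listing counts of flagged and interpolated
#'   samples.
#' @export
clean_recording <- function(rec, cfg = cleaning_config()) {
  if (isTRUE(attr(rec, "cleaned"))) return(rec)
  n_invalid0 <- sum(!rec$samples$valid)
  rec <- flag_artifacts(rec, cfg)
  n_flagged <- sum(!rec$samples$valid) - n_invalid0
  rec <- interpolate_gaps(rec, cfg)
  n_interp <- sum(rec$samples$interpolated)
  rec <- smooth_recording(rec, cfg)
  attr(rec, "cleaned") <- TRUE
  attr(rec, "cleaning_report") <- list(
    subject_id = rec$subject_id, eye = rec$eye,
    n_samples = nrow(rec$samples),
    n_invalid_input = n_invalid0,
    n_flagged_velocity = n_flagged,
    n_interpolated = n_interp,
    n_invalid_final = sum(!rec$samples$valid)
  )
  rec
}
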