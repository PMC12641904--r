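# Fixed schedule constants (milliseconds). The stimulation protocol is fully
# determined by design: every bright epoch lasts 3 s, ramp darks grow by
# 100 ms per cycle for 50 cycles, three long tail darks follow, and the
# 100 ms measurement is repeated 10 times at the end.
.BRIGHT_MS <- 3000L
.RAMP_CYCLES <- 50L
.RAMP_STEP_MS <- 100L
.TAIL_DARK_MS <- c(7000L, 10000L, 15000L)
.REPEAT_CYCLES <- 10L
.REPEAT_DARK_MS <- 100L

#' Build the incrementing bright/dark stimulation protocol
#'
#' Constructs the full stimulation schedule: 50 ramp cycles of 3000 ms bright
#' followed by dark of `100 * k` ms for cycle `k`; three tail cycles with dark
#' durations 7, 10 and 15 s; and a repeat block of 10 cycles of 3000 ms bright
#' and 100 ms dark. A final 3000 ms bright epoch is appended so that the last
#' dark epoch has a measurable light re-onset.
#'
#' Epoch intervals are half-open `[onset, onset + duration)` in integer
#' milliseconds; epochs tile the protocol with no gaps or overlaps, and levels
#' strictly alternate starting with bright. Luminance is carried as two-level
#' metadata (bright at 150 nits, dark below 1 nit); the analysis never uses
#' the photometric values.
#'
#' @param sample_rate_hz Nominal recording rate attached to the protocol
#'   (default 200 Hz).
#' @return A `plr_protocol` object: a list with an `epochs` tibble
#'   (`index`, `phase`, `level`, `onset_ms`, `duration_ms`, `cycle_id`) and
#'   metadata fields `bright_luminance_nits`, `dark_luminance_nits`,
#'   `sample_rate_hz`. The trailing bright epoch has `cycle_id = NA` as it
#'   closes the schedule without starting a new cycle.
#' @examples
#' p <- build_protocol()
#' protocol_duration_ms(p)
#' @export
build_protocol <- function(sample_rate_hz = 200) {
  dark_ms <- c(
    .RAMP_STEP_MS * seq_len(.RAMP_CYCLES),
    .TAIL_DARK_MS,
    rep(.REPEAT_DARK_MS, .REPEAT_CYCLES)
  )
  phase <- c(
    rep("ramp", .RAMP_CYCLES),
    rep("tail", length(.TAIL_DARK_MS)),
    rep("repeat", .REPEAT_CYCLES)
  )
  n_cyc <- length(dark_ms)

  duration <- as.integer(rbind(rep(.BRIGHT_MS, n_cyc), dark_ms))
  level <- rep(c("bright", "dark"), n_cyc)
  epoch_phase <- rep(phase, each = 2L)
  cycle_id <- rep(seq_len(n_cyc), each = 2L)

  # closing bright epoch: gives the final repeat dark its re-onset
  duration <- c(duration, .BRIGHT_MS)
  level <- c(level, "bright")
  epoch_phase <- c(epoch_phase, "repeat")
  cycle_id <- c(cycle_id, NA_integer_)

  onset <- cumsum(c(0L, duration[-length(duration)]))
  epochs <- tibble(
    index = seq_along(level) - 1L,
    phase = epoch_phase,
    level = level,
    onset_ms = as.integer(onset),
    duration_ms = as.integer(duration),
    cycle_id = as.integer(cycle_id)
  )
  out <- structure(
    list(
      epochs = epochs,
      bright_luminance_nits = 150,
      dark_luminance_nits = 0,
      sample_rate_hz = sample_rate_hz
    ),
    class = "plr_protocol"
  )
  validate_protocol(out)
  out
}

#' Validate a stimulation protocol
#'
#' Checks the structural invariants: positive integer durations, contiguous
#' half-open epochs, strict bright/dark alternation starting with bright,
#' 3000 ms bright epochs, ramp darks of exactly `100 * k` ms, tail darks of
#' 7/10/15 s and a 10-cycle repeat block of 100 ms darks.
#'
#' @param protocol A `plr_protocol`.
#' @return `protocol`, invisibly. Errors if an invariant is violated.
#' @export
validate_protocol <- function(protocol) {
  stopifnot(inherits(protocol, "plr_protocol"))
  e <- protocol$epochs
  if (any(e$duration_ms <= 0)) stop("epoch durations must be positive")
  if (!all(e$onset_ms[-1] == (e$onset_ms + e$duration_ms)[-nrow(e)])) {
    stop("epochs must tile the protocol with no gaps or overlaps")
  }
  if (!all(e$level == rep(c("bright", "dark"), length.out = nrow(e))) ||
      e$level[1] != "bright") {
    stop("levels must strictly alternate starting with bright")
  }
  if (!all(e$duration_ms[e$level == "bright"] == .BRIGHT_MS)) {
    stop("all bright epochs must last 3000 ms")
  }
  ramp_darks <- e$duration_ms[e$level == "dark" & e$phase == "ramp"]
  if (!identical(as.integer(ramp_darks),
                 as.integer(.RAMP_STEP_MS * seq_len(.RAMP_CYCLES)))) {
    stop("ramp dark durations must be 100 * k ms for k = 1..50")
  }
  tail_darks <- e$duration_ms[e$level == "dark" & e$phase == "tail"]
  if (!identical(as.integer(tail_darks), .TAIL_DARK_MS)) {
    stop("tail dark durations must be 7000, 10000, 15000 ms")
  }
  rep_darks <- e$duration_ms[e$level == "dark" & e$phase == "repeat"]
  if (!identical(as.integer(rep_darks),
                 rep(.REPEAT_DARK_MS, .REPEAT_CYCLES))) {
    stop("repeat block must contain 10 darks of 100 ms")
  }
  invisible(protocol)
}

#' Total protocol duration in milliseconds
#'
#' @param protocol A `plr_protocol`.
#' @return Integer total duration (sum of epoch durations).
#' @export
protocol_duration_ms <- function(protocol) {
  sum(protocol$epochs$duration_ms)
}

#' Light re-onset events of a protocol
#'
#' A re-onset is a dark-to-bright transition: the moment the bright screen
#' returns after a dark epoch. Re-onsets are the time origin for the
#' region-of-interest amplitude measurement.
#'
#' @param protocol A `plr_protocol`.
#' @return A tibble with one row per dark epoch that is followed by a bright
#'   epoch, sorted by time: `time_ms` (onset of the following bright epoch),
#'   `preceding_dark_ms` (the dark epoch's duration), `cycle_id` and `phase`
#'   of the dark epoch.
#' @export
reonset_times <- function(protocol) {
  e <- protocol$epochs
  followed <- e$level == "dark" &
    c(e$level[-1] == "bright", FALSE)
  i <- which(followed)
  tibble(
    time_ms = e$onset_ms[i] + e$duration_ms[i],
    preceding_dark_ms = e$duration_ms[i],
    cycle_id = e$cycle_id[i],
    phase = e$phase[i]
  )
}

#' Stimulus level at a point in time
#'
#' @param protocol A `plr_protocol`.
#' @param t_ms Vector of times in milliseconds; each must satisfy
#'   `0 <= t_ms < protocol_duration_ms(protocol)`.
#' @return Character vector, `"bright"` or `"dark"`, from the epoch whose
#'   half-open interval `[onset, onset + duration)` contains each time.
#' @export
luminance_at <- function(protocol, t_ms) {
  total <- protocol_duration_ms(protocol)
  if (any(t_ms < 0 | t_ms >= total)) {
    stop("t_ms out of range [0, ", total, ")")
  }
  idx <- findInterval(t_ms, protocol$epochs$onset_ms)
  protocol$epochs$level[idx]
}

#' Write / read a protocol as JSON
#'
#' The JSON carries the epoch list plus the luminance and sampling metadata,
#' so a protocol round-trips field-for-field.
#'
#' @param protocol A `plr_protocol`.
#' @param path File path.
#' @return `write_protocol()` returns `path` invisibly; `read_protocol()`
#'   returns a validated `plr_protocol`.
#' @export
write_protocol <- function(protocol, path) {
  obj <- list(
    epochs = protocol$epochs,
    bright_luminance_nits = protocol$bright_luminance_nits,
    dark_luminance_nits = protocol$dark_luminance_nits,
    sample_rate_hz = protocol$sample_rate_hz
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}

#' @rdname write_protocol
#' @export
read_protocol <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  epochs <- tibble::as_tibble(obj$epochs)
  epochs$cycle_id <- as.integer(epochs$cycle_id)
  epochs$index <- as.integer(epochs$index)
  epochs$onset_ms <- as.integer(epochs$onset_ms)
  epochs$duration_ms <- as.integer(epochs$duration_ms)
  out <- structure(
    list(
      epochs = epochs,
      bright_luminance_nits = as.numeric(obj$bright_luminance_nits),
      dark_luminance_nits = as.numeric(obj$dark_luminance_nits),
      sample_rate_hz = as.numeric(obj$sample_rate_hz)
    ),
    class = "plr_protocol"
  )
  validate_protocol(out)
  out
}

#' @export
print.plr_protocol <- function(x, ...) {
  e <- x$epochs
  cat("<plr_protocol>\n")
  cat(sprintf("  %d epochs, %d cycles, %.1f s total\n",
              nrow(e), max(e$cycle_id, na.rm = TRUE),
              protocol_duration_ms(x) / 1000))
  cat(sprintf("  phases: ramp %d / tail %d / repeat %d cycles\n",
              .RAMP_CYCLES, length(.TAIL_DARK_MS), .REPEAT_CYCLES))
  cat(sprintf("  bright %s nits, dark < 1 nit, nominal %g Hz sampling\n",
              format(x$bright_luminance_nits), x$sample_rate_hz))
  invisible(x)
}
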