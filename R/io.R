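#' Write recordings to long-format CSV
#'
#' Columns: `subject_id`, `eye`, `t_ms`, `diameter_mm`, `valid`. Invalid
#' samples are written with an empty `diameter_mm` field (the file's
#' sentinel). One or several recordings may share a file.
#'
#' @param rec A `plr_recording` or a list of them.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_recording <- function(rec, path) {
  recs <- if (inherits(rec, "plr_recording")) list(rec) else rec
  rows <- dplyr::bind_rows(lapply(recs, function(r) {
    dplyr::mutate(r$samples, subject_id = r$subject_id, eye = r$eye,
                  .before = 1)
  }))
  readr::write_csv(rows, path, na = "")
  invisible(path)
}

#' Read recordings from long-format CSV
#'
#' Inverse of [write_recording()]: `read_recording(write_recording(rec))`
#' reproduces the recording field-for-field. A file without a `valid` column
#' is accepted with a warning, defaulting to all-valid. Non-monotone sample
#' times within a subject/eye are a parse error naming the first bad row.
#'
#' @param path CSV path.
#' @param sample_rate_hz Sampling rate to attach (default inferred from the
#'   median time step).
#' @return A single `plr_recording` if the file holds one subject/eye,
#'   otherwise a named list of recordings.
#' @export
read_recording <- function(path, sample_rate_hz = NULL) {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  need <- c("subject_id", "eye", "t_ms", "diameter_mm")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("recording CSV is missing column(s): ", paste(miss, collapse = ", "))
  }
  if (!"valid" %in% names(df)) {
    warning("no 'valid' column in ", path, "; assuming all samples valid")
    df$valid <- TRUE
  }
  df$valid <- as.logical(df$valid)
  keys <- unique(df[, c("subject_id", "eye")])
  recs <- lapply(seq_len(nrow(keys)), function(i) {
    sub <- df[df$subject_id == keys$subject_id[i] & df$eye == keys$eye[i], ]
    bad <- which(diff(sub$t_ms) <= 0)
    if (length(bad)) {
      stop("non-monotone t_ms for ", keys$subject_id[i], "/", keys$eye[i],
           " at row ", bad[1] + 1)
    }
    sr <- sample_rate_hz
    if (is.null(sr)) sr <- 1000 / stats::median(diff(sub$t_ms))
    structure(
      list(
        subject_id = keys$subject_id[i],
        eye = keys$eye[i],
        sample_rate_hz = sr,
        protocol_ref = NA_character_,
        samples = tibble(t_ms = sub$t_ms, diameter_mm = sub$diameter_mm,
                         valid = sub$valid)
      ),
      class = "plr_recording"
    )
  })
  names(recs) <- paste(keys$subject_id, keys$eye, sep = "/")
  if (length(recs) == 1) recs[[1]] else recs
}

#' Write / read the subject table
#'
#' @param subjects Subject tibble from [simulate_cohort()].
#' @param path CSV path.
#' @return `path` invisibly / the subject tibble.
#' @export
write_subjects <- function(subjects, path) {
  readr::write_csv(subjects, path, na = "")
  invisible(path)
}

#' @rdname write_subjects
#' @export
read_subjects <- function(path) {
  readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
}

#' Write / read an amplitude table
#'
#' Long-format CSV with one row per subject x eye x cycle: `subject_id`,
#' `eye`, `group`, `age_years`, `phase`, `cycle_id`, `dark_ms`, `d_max_mm`,
#' `d_min_mm`, `amplitude`, `missing`, `missing_reason`.
#'
#' @param table Amplitude table tibble.
#' @param path CSV path.
#' @return `path` invisibly / the amplitude tibble.
#' @export
write_amplitude_table <- function(table, path) {
  readr::write_csv(table, path, na = "")
  invisible(path)
}

#' @rdname write_amplitude_table
#' @export
read_amplitude_table <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE,
                        col_types = readr::cols(
                          missing_reason = readr::col_character(),
                          eye = readr::col_character()
                        ))
  df$missing <- as.logical(df$missing)
  tibble::as_tibble(df)
}
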