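#' Write a recording to delimited text
#'
#' One file per subject with header `time_s, pca_velocity, mca_velocity,
#' abp, co2` (comma-separated, decimal point, UTF-8).
#'
#' @param subject A `vefr_subject` at waveform fidelity, or a bare data
#'   frame with the five columns.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_recording <- function(subject, path) {
  df <- if (is.data.frame(subject)) subject else subject$recording$data
  need <- c("time_s", "pca_velocity", "mca_velocity", "abp", "co2")
  stopifnot(all(need %in% names(df)))
  data.table::fwrite(df[need], path)
  invisible(path)
}

#' Read a recording from delimited text
#'
#' Validates the header, numeric content and sampling uniformity; the sample
#' rate is inferred from the time column.
#'
#' @param path File produced by [write_recording()] (or equivalent).
#' @param subject_id Identifier (defaults to the file name without extension).
#' @param rel_tol Relative tolerance on time-step uniformity.
#' @return A list (`vefr_recording`): `subject_id`, `data`, `sample_rate`,
#'   `t0` (time of the first sample).
#' @export
read_recording <- function(path, subject_id = NULL, rel_tol = 1e-6) {
  if (is.null(subject_id))
    subject_id <- sub("\\.[^.]*$", "", basename(path))
  dt <- data.table::fread(path, colClasses = "character", showProgress = FALSE)
  need <- c("time_s", "pca_velocity", "mca_velocity", "abp", "co2")
  miss <- setdiff(need, names(dt))
  if (length(miss))
    stop("missing channel column(s): ", paste(miss, collapse = ", "))
  df <- as.data.frame(dt)[need]
  for (nm in need) {
    v <- suppressWarnings(as.numeric(df[[nm]]))
    if (anyNA(v)) {
      bad <- which(is.na(v))[1]
      stop(sprintf("non-numeric value in column '%s' at data row %d: '%s'",
                   nm, bad, df[[nm]][bad]))
    }
    df[[nm]] <- v
  }
  steps <- diff(df$time_s)
  if (length(steps) < 1) stop("recording must contain at least 2 samples")
  med <- stats::median(steps)
  off <- which(abs(steps - med) > rel_tol * med)
  if (length(off))
    stop(sprintf("non-uniform sampling: first offending gap after row %d (dt = %g, expected %g)",
                 off[1], steps[off[1]], med))
  structure(list(subject_id = subject_id, data = df,
                 sample_rate = 1 / med, t0 = df$time_s[1]),
            class = "vefr_recording")
}

#' Write subject metadata
#' @param metadata Data frame (subject_id, group, age, sex, bmi, smoking).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_metadata <- function(metadata, path) {
  data.table::fwrite(metadata, path)
  invisible(path)
}

#' Read subject metadata
#' @param path File produced by [write_metadata()].
#' @return Data frame.
#' @export
read_metadata <- function(path) {
  df <- as.data.frame(data.table::fread(path, showProgress = FALSE))
  if (!all(c("subject_id", "group") %in% names(df)))
    stop("metadata must contain subject_id and group columns")
  df
}

#' Write a simulated cohort to a directory
#'
#' Waveform recordings become one CSV per subject plus `metadata.csv`; the
#' programmed truth is also written (`truth.csv`) so recovery studies remain
#' reproducible from disk.
#'
#' @param cohort A [simulate_cohort()] result (waveform fidelity).
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "vefr_cohort"))
  if (cohort$config$fidelity != "waveform")
    stop("only waveform-fidelity cohorts are written as recordings")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (s in cohort$subjects)
    write_recording(s, file.path(dir, paste0(s$subject_id, ".csv")))
  write_metadata(cohort$metadata, file.path(dir, "metadata.csv"))
  data.table::fwrite(cohort$truth, file.path(dir, "truth.csv"))
  invisible(dir)
}
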