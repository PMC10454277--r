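#' Map the stimulation protocol onto the recording timeline
#'
#' Produces per-cycle OFF/ON windows and the analysis sub-windows used for
#' the evoked response: the rest window is the last 5 s of OFF and the
#' stimulation window the last 10 s of ON. All windows are half-open
#' `[start, end)` in seconds from recording start. On toy protocols whose
#' phases are shorter than the analysis windows, the analysis window is the
#' whole phase and a warning is emitted.
#'
#' @param protocol A [stim_protocol()] object.
#' @param trigger_time Protocol start relative to recording start (s).
#' @param total_duration Optional recording duration; if given and shorter
#'   than the protocol span an error lists the truncated cycles.
#' @param rest_window_s Rest analysis window length, seconds (default 5).
#' @param stim_window_s Stimulation analysis window length, seconds (default 10).
#' @return A `cycle_segmentation` data frame with one row per cycle:
#'   window boundaries, `included` flag and `exclusion_reason`.
#' @export
#' @examples
#' seg <- segment(stim_protocol(), trigger_time = 0)
#' seg[1, c("off_start", "off_end", "on_start", "on_end")]   # [0,20) / [20,50)
segment <- function(protocol, trigger_time = 0, total_duration = NULL,
                    rest_window_s = 5, stim_window_s = 10) {
  stopifnot(trigger_time >= 0, rest_window_s > 0, stim_window_s > 0)
  off <- protocol$off_duration; on <- protocol$on_duration
  nc <- protocol$n_cycles
  span <- off + on
  cyc <- seq_len(nc)
  off_start <- trigger_time + (cyc - 1) * span
  off_end <- off_start + off
  on_start <- off_end
  on_end <- on_start + on

  if (!is.null(total_duration) && total_duration < trigger_time + nc * span) {
    trunc <- cyc[on_end > total_duration]
    stop(sprintf("recording (%.1f s) shorter than protocol span; truncated cycle(s): %s",
                 total_duration, paste(trunc, collapse = ", ")))
  }

  rw <- rest_window_s; sw <- stim_window_s
  if (off < rest_window_s) {
    warning("OFF phase shorter than the rest analysis window; using the whole OFF phase")
    rw <- off
  }
  if (on < stim_window_s) {
    warning("ON phase shorter than the stimulation analysis window; using the whole ON phase")
    sw <- on
  }

  seg <- data.frame(cycle = cyc,
                    off_start = off_start, off_end = off_end,
                    on_start = on_start, on_end = on_end,
                    rest_start = off_end - rw, rest_end = off_end,
                    stim_start = on_end - sw, stim_end = on_end,
                    included = TRUE, exclusion_reason = "none",
                    stringsAsFactors = FALSE)
  attr(seg, "protocol") <- protocol
  attr(seg, "trigger_time") <- trigger_time
  class(seg) <- c("cycle_segmentation", "data.frame")
  seg
}

#' Default thresholds for artifact-cycle exclusion
#'
#' @param snr_min Minimum cycle SNR: median beat amplitude over the largest
#'   1-s-windowed robust noise estimate (second-difference MAD).
#' @param max_missing_frac Maximum tolerated fraction of expected beats
#'   missing in a cycle (expectation from the recording's median heart rate).
#' @param dropout_floor_frac Envelope values below this fraction of the
#'   cycle-wide median count as signal dropout.
#' @param dropout_min_s Minimum dropout run length (s) that excludes a cycle.
#' @param gap_factor At beat-level fidelity (no envelope available), an
#'   inter-beat gap longer than `max(dropout_min_s, gap_factor x median
#'   inter-beat interval)` counts as dropout.
#' @return A list of thresholds for [exclude_artifact_cycles()].
#' @export
exclusion_criteria <- function(snr_min = 3, max_missing_frac = 0.10,
                               dropout_floor_frac = 0.10, dropout_min_s = 1,
                               gap_factor = 1.6) {
  stopifnot(snr_min >= 0, max_missing_frac >= 0, max_missing_frac <= 1,
            dropout_floor_frac >= 0, dropout_min_s > 0, gap_factor > 1)
  list(snr_min = snr_min, max_missing_frac = max_missing_frac,
       dropout_floor_frac = dropout_floor_frac, dropout_min_s = dropout_min_s,
       gap_factor = gap_factor)
}

# Robust noise estimate per 1 s bin: MAD of second differences / sqrt(6)
# (second differencing annihilates slow beat morphology, sqrt(6) restores the
# SD of white noise). The cycle estimate is the worst (largest) bin, so short
# spike bursts are not hidden by the median over a long cycle.
.windowed_noise <- function(x, sample_rate, win_s = 1) {
  d2 <- diff(x, differences = 2)
  n <- length(d2)
  if (n < 4) return(stats::mad(d2) / sqrt(6))
  win <- max(8L, as.integer(round(win_s * sample_rate)))
  starts <- seq(1L, n, by = win)
  worst <- 0
  for (s in starts) {
    seg <- d2[s:min(n, s + win - 1L)]
    worst <- max(worst, stats::mad(seg) / sqrt(6))
  }
  worst
}

# Runs of `below` (logical) longer than min_len samples, closing gaps up to
# gap_len samples; returns matrix of [start, end] sample indices.
.long_runs <- function(below, min_len, gap_len) {
  r <- rle(below)
  # close short TRUE-interruptions of FALSE? we close short FALSE gaps inside TRUE runs
  if (length(r$lengths) > 2) {
    inner <- 2:(length(r$lengths) - 1)
    fix <- inner[!r$values[inner] & r$lengths[inner] <= gap_len]
    r$values[fix] <- TRUE
    r <- rle(inverse.rle(r))
  }
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & r$lengths > min_len
  cbind(start = starts[keep], end = ends[keep])
}

#' Exclude artifact-contaminated cycles
#'
#' Operationalizes the qualitative rule that cycles affected by artifacts
#' which significantly depress the signal-to-noise ratio are excluded from
#' the evoked-response analysis. A cycle is excluded iff any of:
#' (a) its envelope SNR falls below `snr_min`;
#' (b) more than `max_missing_frac` of its expected beats are missing
#'     (expectation from the recording-wide median heart rate);
#' (c) a signal dropout (envelope below `dropout_floor_frac` of its median
#'     for longer than `dropout_min_s`) intersects the cycle.
#' Decisions are per cycle, never per subject. Without an envelope (beat-level
#' data) criterion (a) is unavailable and dropout is detected from inter-beat
#' gaps instead.
#'
#' @param segmentation A [segment()] result.
#' @param beats A `beat_series` from the same recording.
#' @param envelope Optional raw velocity envelope (for criteria (a) and (c)).
#' @param sample_rate Envelope sample rate in Hz (required with `envelope`).
#' @param t0 Time of the first envelope sample (s).
#' @param criteria Thresholds from [exclusion_criteria()].
#' @return The segmentation with updated `included` / `exclusion_reason`.
#' @export
exclude_artifact_cycles <- function(segmentation, beats, envelope = NULL,
                                    sample_rate = NULL, t0 = 0,
                                    criteria = exclusion_criteria()) {
  seg <- segmentation
  bt <- beats$time
  hr_med <- stats::median(beats$hr, na.rm = TRUE)
  if (!is.finite(hr_med) || hr_med <= 0) hr_med <- NA_real_
  med_period <- if (is.finite(hr_med)) 60 / hr_med else NA_real_

  dropout_spans <- NULL
  env_median <- NA_real_
  if (!is.null(envelope)) {
    stopifnot(!is.null(sample_rate))
    env_median <- stats::median(envelope)
    floor_v <- criteria$dropout_floor_frac * env_median
    below <- envelope < floor_v
    runs <- .long_runs(below,
                       min_len = as.integer(criteria$dropout_min_s * sample_rate),
                       gap_len = as.integer(round(0.1 * sample_rate)))
    if (nrow(runs))
      dropout_spans <- cbind(t0 + (runs[, 1] - 1) / sample_rate,
                             t0 + (runs[, 2] - 1) / sample_rate)
  }

  for (i in seq_len(nrow(seg))) {
    if (!seg$included[i]) next
    w0 <- seg$off_start[i]; w1 <- seg$on_end[i]
    in_cyc <- bt >= w0 & bt < w1
    nb <- sum(in_cyc)
    reason <- "none"

    # (c) dropout
    if (!is.null(dropout_spans)) {
      if (any(dropout_spans[, 1] < w1 & dropout_spans[, 2] > w0)) reason <- "dropout"
    } else if (is.finite(med_period) && nb >= 2) {
      edges <- c(w0, bt[in_cyc], w1)     # beat times are already ascending
      gap_thr <- max(criteria$dropout_min_s, criteria$gap_factor * med_period)
      if (max(diff(edges)) > gap_thr) reason <- "dropout"
    }

    # (b) missing beats
    if (reason == "none" && is.finite(hr_med)) {
      expected <- floor((w1 - w0) * hr_med / 60)
      if (expected > 0 && (1 - nb / expected) > criteria$max_missing_frac)
        reason <- "beat_failure"
    }
    if (reason == "none" && nb == 0) reason <- "beat_failure"

    # (a) SNR
    if (reason == "none" && !is.null(envelope)) {
      i0 <- max(1L, as.integer(floor((w0 - t0) * sample_rate)) + 1L)
      i1 <- min(length(envelope), as.integer(ceiling((w1 - t0) * sample_rate)))
      if (i1 > i0 + 8L) {
        amp <- beats$systolic[in_cyc] - beats$diastolic[in_cyc]
        amp_med <- if (length(amp)) stats::median(amp) else NA_real_
        noise <- .windowed_noise(envelope[i0:i1], sample_rate)
        snr <- if (!is.finite(amp_med)) 0 else if (noise <= 0) Inf else amp_med / noise
        if (snr < criteria$snr_min) reason <- "low_snr"
      }
    }

    if (reason != "none") {
      seg$included[i] <- FALSE
      seg$exclusion_reason[i] <- reason
    }
  }
  if (!any(seg$included))
    attr(seg, "unusable") <- TRUE
  seg
}
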