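#' Visually evoked flow-velocity response (percent)
#'
#' Relative change of blood flow velocity during the stimulation plateau
#' with respect to rest: `(v_stimul - v_rest) / v_rest * 100`.
#'
#' @param v_stimul Average velocity during the last 10 s of stimulation (cm/s).
#' @param v_rest Average velocity during the last 5 s of rest (cm/s).
#' @return Response in percent of the rest value. Vectorized.
#' @export
#' @examples
#' compute_vefr(36.45, 32.4)   # 12.5
compute_vefr <- function(v_stimul, v_rest) {
  if (any(v_rest <= 0)) stop("v_rest must be > 0")
  (v_stimul - v_rest) / v_rest * 100
}

# Assign event times to windows [starts, ends); NA when outside every window.
.window_index <- function(t, starts, ends) {
  i <- findInterval(t, starts)
  ok <- i >= 1 & t < ends[pmax(i, 1L)]
  ifelse(ok, i, NA_integer_)
}

# Window means of the three velocity indices over beats; returns 3 x n_cycles.
.window_index_means <- function(beats, starts, ends, n_cycles) {
  idx <- .window_index(beats$time, starts, ends)
  keep <- !is.na(idx)
  out <- matrix(NA_real_, 3, n_cycles,
                dimnames = list(c("systolic", "mean", "diastolic"), NULL))
  if (!any(keep)) return(out)
  m <- rowsum(cbind(beats$systolic, beats$mean, beats$diastolic)[keep, , drop = FALSE],
              idx[keep])
  present <- as.integer(rownames(m))
  n <- tabulate(idx[keep], nbins = n_cycles)
  out[1, present] <- m[, 1] / n[present]
  out[2, present] <- m[, 2] / n[present]
  out[3, present] <- m[, 3] / n[present]
  out
}

#' Per-cycle VEFR for the three velocity indices
#'
#' For every included cycle, the rest value of each velocity index (peak
#' systolic, mean, end diastolic) is its average over the beats falling in
#' the rest analysis window, the stimulation value its average over the
#' stimulation analysis window, and the response their relative change
#' ([compute_vefr()]). Rows for excluded cycles carry `included = FALSE` and
#' no response; an included cycle with an empty analysis window is demoted
#' to excluded with reason `"beat_failure"`.
#'
#' @param beats A [beat_series()].
#' @param segmentation A [segment()] result (after artifact exclusion).
#' @return A `vefr_table` data frame keyed by (artery, index, cycle) with
#'   columns `v_rest`, `v_stimul`, `response`, `included`, `exclusion_reason`.
#' @export
cycle_vefr <- function(beats, segmentation) {
  seg <- segmentation
  nc <- nrow(seg)
  rest <- .window_index_means(beats, seg$rest_start, seg$rest_end, nc)
  stim <- .window_index_means(beats, seg$stim_start, seg$stim_end, nc)
  artery <- attr(beats, "artery")
  if (is.null(artery)) artery <- "PCA"

  idx_names <- c("systolic", "mean", "diastolic")
  out <- .fast_df(list(
    artery = rep(artery, 3L * nc),
    index = rep(idx_names, times = nc),
    cycle = rep(seg$cycle, each = 3),
    v_rest = as.vector(rest),         # column-major: 3 indices per cycle
    v_stimul = as.vector(stim)))
  out$included <- rep(seg$included, each = 3)
  out$exclusion_reason <- rep(seg$exclusion_reason, each = 3)

  bad <- out$included & (!is.finite(out$v_rest) | !is.finite(out$v_stimul) |
                           out$v_rest <= 0)
  out$included[bad] <- FALSE
  out$exclusion_reason[bad] <- "beat_failure"

  out$response <- NA_real_
  ok <- out$included
  out$response[ok] <- compute_vefr(out$v_stimul[ok], out$v_rest[ok])
  out$v_rest[!ok & !is.finite(out$v_rest)] <- NA_real_
  class(out) <- c("vefr_table", "data.frame")
  out
}

#' Per-subject average response over included cycles
#'
#' @param vefr A `vefr_table` (possibly spanning several arteries).
#' @return A data frame with one row per (artery, index): the unweighted
#'   arithmetic mean response over included cycles and the number of cycles
#'   included. Zero included cycles raises a warning and returns zero rows
#'   (the subject is unusable for cohort statistics).
#' @export
subject_average <- function(vefr) {
  inc <- vefr[vefr$included, , drop = FALSE]
  if (!nrow(inc)) {
    warning("no included cycles; subject unusable")
    return(data.frame(artery = character(), index = character(),
                      response = numeric(), n_cycles_included = integer()))
  }
  agg <- stats::aggregate(inc$response,
                          by = list(artery = inc$artery, index = inc$index),
                          FUN = mean)
  n <- stats::aggregate(inc$response,
                        by = list(artery = inc$artery, index = inc$index),
                        FUN = length)
  out <- data.frame(artery = agg$artery, index = agg$index,
                    response = agg$x, n_cycles_included = as.integer(n$x),
                    stringsAsFactors = FALSE)
  out[order(out$artery, match(out$index, c("systolic", "mean", "diastolic"))), ,
      drop = FALSE]
}

# Centred moving average of y(t) over a +/- width/2 time window (irregular t).
.time_smooth <- function(t, y, width) {
  lo <- findInterval(t - width / 2, t) + 1L
  hi <- findInterval(t + width / 2, t)
  cs <- cumsum(y)
  (cs[hi] - ifelse(lo > 1, cs[lo - 1L], 0)) / (hi - lo + 1L)
}

#' Early-phase response over 10 s from response onset
#'
#' Per included cycle, the relative mean-velocity time course against the
#' cycle's rest value is smoothed with a 2 s moving average; the onset is
#' the first time after stimulus start at which the smoothed response
#' exceeds `max(threshold_sd x baseline SD, floor_pp)` and stays above it
#' for at least `sustain_s`. The early-phase response of each index is its
#' mean relative change over `[onset, onset + horizon_s)` (clipped at the
#' ON-phase end), averaged over cycles with a detected onset.
#'
#' @param beats A [beat_series()].
#' @param segmentation A [segment()] result.
#' @param smooth_width Moving-average width in seconds.
#' @param threshold_sd Onset threshold in baseline SDs of the smoothed trace.
#' @param sustain_s Time the trace must stay above threshold (s).
#' @param floor_pp Absolute threshold floor in percentage points (guards the
#'   zero-noise case where the baseline SD vanishes).
#' @param horizon_s Early-phase horizon from onset (s).
#' @param min_baseline_beats Minimum number of rest-window beats per cycle.
#' @return A list with `response` (named vector, percent per index),
#'   `onsets` (per-cycle onset latency from ON start, NA when undetected)
#'   and `n_cycles_used`.
#' @export
early_phase_response <- function(beats, segmentation, smooth_width = 2,
                                 threshold_sd = 2, sustain_s = 1,
                                 floor_pp = 0.1, horizon_s = 10,
                                 min_baseline_beats = 5) {
  seg <- segmentation
  idx_names <- c("systolic", "mean", "diastolic")
  acc <- matrix(NA_real_, nrow(seg), 3, dimnames = list(NULL, idx_names))
  onsets <- rep(NA_real_, nrow(seg))
  for (i in seq_len(nrow(seg))) {
    if (!seg$included[i]) next
    in_cyc <- beats$time >= seg$off_start[i] & beats$time < seg$on_end[i]
    b <- beats[in_cyc, , drop = FALSE]
    in_rest <- b$time >= seg$rest_start[i] & b$time < seg$rest_end[i]
    if (sum(in_rest) < min_baseline_beats) next
    v_rest <- colMeans(b[in_rest, c("systolic", "mean", "diastolic"), drop = FALSE])
    if (any(v_rest <= 0)) next
    rel_mean <- (b$mean - v_rest["mean"]) / v_rest["mean"] * 100
    sm <- .time_smooth(b$time, rel_mean, smooth_width)
    thr <- max(threshold_sd * stats::sd(sm[in_rest]), floor_pp)
    if (!is.finite(thr)) thr <- floor_pp

    cand <- which(b$time >= seg$on_start[i] & sm > thr)
    onset <- NA_real_
    for (j in cand) {
      upto <- b$time >= b$time[j] & b$time <= b$time[j] + sustain_s
      if (all(sm[upto] > thr)) { onset <- b$time[j]; break }
    }
    if (is.na(onset)) next
    onsets[i] <- onset - seg$on_start[i]
    w1 <- min(onset + horizon_s, seg$on_end[i])
    in_w <- b$time >= onset & b$time < w1
    if (!any(in_w)) next
    for (nm in idx_names)
      acc[i, nm] <- mean((b[[nm]][in_w] - v_rest[nm]) / v_rest[nm] * 100)
  }
  used <- which(rowSums(is.finite(acc)) == 3)
  resp <- if (length(used)) colMeans(acc[used, , drop = FALSE]) else
    stats::setNames(rep(NA_real_, 3), idx_names)
  list(response = resp, onsets = onsets, n_cycles_used = length(used))
}

#' Cycle-averaged relative velocity time course
#'
#' Each included cycle's beat series is expressed as percent change against
#' that cycle's rest value, interpolated onto a common grid around the
#' OFF-to-ON switch, and averaged pointwise over cycles.
#'
#' @param beats A [beat_series()].
#' @param segmentation A [segment()] result.
#' @param grid_hz Grid rate in Hz (default 2).
#' @return A data frame `time` (seconds relative to the switch, spanning
#'   `[-off_duration, on_duration]`) and one column per velocity index, in
#'   percent of baseline.
#' @export
relative_time_course <- function(beats, segmentation, grid_hz = 2) {
  seg <- segmentation
  protocol <- attr(seg, "protocol")
  off <- if (!is.null(protocol)) protocol$off_duration else seg$off_end[1] - seg$off_start[1]
  on <- if (!is.null(protocol)) protocol$on_duration else seg$on_end[1] - seg$on_start[1]
  grid <- seq(-off, on, by = 1 / grid_hz)
  idx_names <- c("systolic", "mean", "diastolic")
  sums <- matrix(0, length(grid), 3, dimnames = list(NULL, idx_names))
  nuse <- 0L
  for (i in seq_len(nrow(seg))) {
    if (!seg$included[i]) next
    in_cyc <- beats$time >= seg$off_start[i] & beats$time < seg$on_end[i]
    b <- beats[in_cyc, , drop = FALSE]
    if (nrow(b) < 4) next
    in_rest <- b$time >= seg$rest_start[i] & b$time < seg$rest_end[i]
    if (!any(in_rest)) next
    v_rest <- colMeans(b[in_rest, idx_names, drop = FALSE])
    if (any(v_rest <= 0)) next
    tt <- b$time - seg$on_start[i]
    for (nm in idx_names) {
      rel <- (b[[nm]] - v_rest[nm]) / v_rest[nm] * 100
      sums[, nm] <- sums[, nm] + stats::approx(tt, rel, xout = grid, rule = 2)$y
    }
    nuse <- nuse + 1L
  }
  if (nuse == 0L) stop("no usable cycles for the time course")
  out <- data.frame(time = grid, sums / nuse)
  names(out) <- c("time", idx_names)
  out
}
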