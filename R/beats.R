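# data.frame() spends most of its time on checks and deparsing; the hot
# constructors below run millions of times in Monte-Carlo studies.
.fast_df <- function(x) {
  structure(x, class = "data.frame",
            row.names = c(NA_integer_, -length(x[[1L]])))
}

#' Mean velocity from systolic and diastolic velocities
#'
#' The classical time-weighted estimate of mean flow velocity over the
#' cardiac cycle: `(systolic + 2 * diastolic) / 3`.
#'
#' @param systolic Peak systolic velocity (cm/s), vectorized.
#' @param diastolic End diastolic velocity (cm/s), vectorized.
#' @return Mean velocity in cm/s.
#' @export
#' @examples
#' mean_velocity(60, 30)   # 40
mean_velocity <- function(systolic, diastolic) {
  if (any(diastolic < 0)) stop("diastolic velocity must be >= 0")
  if (any(systolic < diastolic)) stop("systolic velocity must be >= diastolic velocity")
  (systolic + 2 * diastolic) / 3
}

#' Construct a per-beat velocity series
#'
#' Container for beat-to-beat velocity indices of one artery: systolic peak
#' times, peak systolic and end diastolic velocities, the derived mean
#' velocity, and instantaneous heart rate from inter-peak intervals (the
#' first beat has no rate).
#'
#' @param time Systolic peak times in seconds, strictly increasing.
#' @param systolic Peak systolic velocities (cm/s).
#' @param diastolic End diastolic velocities (cm/s).
#' @param artery `"PCA"` or `"MCA"`.
#' @param quality Character vector of quality flags (empty when clean).
#' @return A `beat_series` data frame with columns
#'   `time, systolic, diastolic, mean, hr`.
#' @export
beat_series <- function(time, systolic, diastolic, artery = "PCA",
                        quality = character()) {
  stopifnot(length(time) == length(systolic), length(time) == length(diastolic))
  if (length(time) > 1 && any(diff(time) <= 0)) stop("peak times must be strictly increasing")
  hr <- if (length(time) > 1) c(NA_real_, 60 / diff(time)) else rep(NA_real_, length(time))
  bs <- .fast_df(list(
    time = time, systolic = systolic, diastolic = diastolic,
    mean = if (length(time)) mean_velocity(systolic, diastolic) else numeric(),
    hr = hr))
  attr(bs, "artery") <- match.arg(artery, c("PCA", "MCA"))
  attr(bs, "quality") <- quality
  class(bs) <- c("beat_series", "data.frame")
  bs
}

# Strict-ish local maxima (allow right-side ties so sampled plateaus keep
# their first sample); returns indices into x.
.local_maxima <- function(x) {
  n <- length(x)
  if (n < 3) return(integer())
  which(x[2:(n - 1)] > x[1:(n - 2)] & x[2:(n - 1)] >= x[3:n]) + 1L
}

# Greedy tallest-first selection enforcing a minimum inter-peak distance.
.select_peaks <- function(x, cand, min_dist) {
  ord <- cand[order(x[cand], decreasing = TRUE)]
  n <- length(x)
  blocked <- logical(n)
  keep <- logical(length(ord))
  for (k in seq_along(ord)) {
    i <- ord[k]
    if (blocked[i]) next
    keep[k] <- TRUE
    blocked[max(1L, i - min_dist):min(n, i + min_dist)] <- TRUE
  }
  sort(ord[keep])
}

# Sub-sample peak-time refinement by parabolic interpolation around sample i.
.refine_peak_times <- function(x, idx, dt) {
  off <- numeric(length(idx))
  ok <- idx > 1L & idx < length(x)
  i <- idx[ok]
  denom <- x[i - 1L] - 2 * x[i] + x[i + 1L]
  d <- ifelse(abs(denom) > .Machine$double.eps,
              0.5 * (x[i - 1L] - x[i + 1L]) / denom, 0)
  off[ok] <- pmax(-0.5, pmin(0.5, d))
  (idx - 1L + off) * dt
}

#' Detect heartbeats in a velocity envelope
#'
#' Systolic peaks are local maxima separated by at least the shortest
#' physiological beat interval (`60 / max(hr_bounds)` s), retained only if
#' their beat amplitude (peak minus preceding valley) exceeds an adaptive
#' threshold (`min_amplitude_frac` of the median beat amplitude within a
#' +/-5 s neighbourhood). The end diastolic velocity of each beat is the
#' envelope minimum between the previous peak and the current one (the
#' pre-upstroke valley). Peak times are refined to sub-sample precision by
#' parabolic interpolation, and instantaneous heart rate is 60 over the
#' inter-peak interval.
#'
#' @param envelope Uniformly sampled velocity envelope (cm/s).
#' @param sample_rate Sampling rate in Hz.
#' @param hr_bounds Plausible heart-rate interval in beats/min.
#' @param min_amplitude_frac Adaptive amplitude threshold fraction.
#' @param t0 Time of the first sample (s).
#' @param artery Artery label carried on the result.
#' @return A [beat_series()]; empty with quality flag `"no_beats"` when no
#'   peaks are found, flagged `"implausible_hr"` when the rate leaves
#'   `hr_bounds` for more than 3 consecutive beats.
#' @export
detect_beats <- function(envelope, sample_rate, hr_bounds = c(40, 150),
                         min_amplitude_frac = 0.3, t0 = 0, artery = "PCA") {
  stopifnot(sample_rate > 0, length(hr_bounds) == 2, hr_bounds[1] < hr_bounds[2])
  if (length(envelope) < 5 * sample_rate)
    stop("signal shorter than 5 s")
  dt <- 1 / sample_rate
  cand <- .local_maxima(envelope)
  if (!length(cand))
    return(beat_series(numeric(), numeric(), numeric(), artery, quality = "no_beats"))

  min_dist <- max(1L, as.integer(round(60 / hr_bounds[2] * sample_rate)))
  pk <- .select_peaks(envelope, cand, min_dist)

  valleys <- function(pk) {
    v <- numeric(length(pk))
    prev <- c(max(1L, pk[1] - 2L * min_dist), pk[-length(pk)])
    for (i in seq_along(pk)) v[i] <- min(envelope[prev[i]:pk[i]])
    v
  }
  # adaptive amplitude gate within +/- 5 s of each peak, iterated to a fixed
  # point: when spurious noise peaks outnumber real beats they depress the
  # windowed median, so re-estimate it from survivors until stable
  for (pass in 1:4) {
    val <- valleys(pk)
    amp <- envelope[pk] - val
    tpk <- (pk - 1L) * dt
    lo <- findInterval(tpk - 5, tpk) + 1L
    hi <- findInterval(tpk + 5, tpk)
    med_amp <- vapply(seq_along(pk),
                      function(i) stats::median(amp[lo[i]:hi[i]]), numeric(1))
    keep <- amp >= min_amplitude_frac * med_amp
    pk <- pk[keep]
    if (!length(pk))
      return(beat_series(numeric(), numeric(), numeric(), artery, quality = "no_beats"))
    if (all(keep)) break
  }
  val <- valleys(pk)

  times <- t0 + .refine_peak_times(envelope, pk, dt)
  # artifacted signals can dip below zero; velocities are physically >= 0
  dia <- pmax(val, 0)
  sys <- pmax(envelope[pk], dia)
  bs <- beat_series(times, sys, dia, artery)

  hr <- bs$hr[-1]
  bad <- !is.na(hr) & (hr < hr_bounds[1] | hr > hr_bounds[2])
  if (length(bad)) {
    r <- rle(bad)
    if (any(r$values & r$lengths > 3))
      attr(bs, "quality") <- c(attr(bs, "quality"), "implausible_hr")
  }
  bs
}

#' Detect breaths and end-tidal CO2 in a capnogram
#'
#' Breath peaks are local maxima of the CO2 waveform separated by at least
#' `60 / max(rr_bounds)` s; the end-tidal CO2 of each breath is the peak
#' amplitude (parabolically refined).
#'
#' @param co2 Uniformly sampled CO2 partial-pressure waveform (mmHg).
#' @param sample_rate Sampling rate in Hz.
#' @param rr_bounds Plausible respiratory-rate interval in breaths/min.
#' @param min_amplitude_frac Adaptive amplitude threshold fraction.
#' @param t0 Time of the first sample (s).
#' @return A `breath_series` data frame (`time`, `etco2`) with a `quality`
#'   attribute; empty with flag `"no_breaths"` on a flat signal.
#' @export
detect_breaths <- function(co2, sample_rate, rr_bounds = c(6, 30),
                           min_amplitude_frac = 0.3, t0 = 0) {
  stopifnot(sample_rate > 0, rr_bounds[1] < rr_bounds[2])
  dt <- 1 / sample_rate
  empty <- function(flag) {
    b <- data.frame(time = numeric(), etco2 = numeric())
    attr(b, "quality") <- flag
    class(b) <- c("breath_series", "data.frame")
    b
  }
  cand <- .local_maxima(co2)
  if (!length(cand)) return(empty("no_breaths"))
  min_dist <- max(1L, as.integer(round(60 / rr_bounds[2] * sample_rate)))
  pk <- .select_peaks(co2, cand, min_dist)
  prev <- c(max(1L, pk[1] - 2L * min_dist), pk[-length(pk)])
  val <- vapply(seq_along(pk), function(i) min(co2[prev[i]:pk[i]]), numeric(1))
  amp <- co2[pk] - val
  keep <- amp >= min_amplitude_frac * stats::median(amp)
  pk <- pk[keep]
  if (!length(pk)) return(empty("no_breaths"))

  # refined peak value via the same parabola used for the time refinement
  value <- co2[pk]
  ok <- pk > 1L & pk < length(co2)
  i <- pk[ok]
  denom <- co2[i - 1L] - 2 * co2[i] + co2[i + 1L]
  adj <- ifelse(abs(denom) > .Machine$double.eps,
                (co2[i - 1L] - co2[i + 1L])^2 / (8 * abs(denom)), 0)
  value[ok] <- value[ok] + pmin(adj, abs(denom))

  b <- data.frame(time = t0 + .refine_peak_times(co2, pk, dt), etco2 = value)
  attr(b, "quality") <- character()
  class(b) <- c("breath_series", "data.frame")
  b
}

#' Phase-wise means of systemic variables
#'
#' Mean arterial pressure, end-tidal CO2 and heart rate averaged within each
#' ON and OFF phase of every cycle, plus across-cycle phase averages.
#' Membership uses the half-open window `[start, end)` on event (beat/breath
#' peak) times; MAP is the time average of pressure samples in the window.
#'
#' @param beats A [beat_series()] (PCA by convention: heart rate is derived
#'   from PCA inter-peak times).
#' @param breaths A `breath_series` from [detect_breaths()].
#' @param abp Arterial blood pressure samples (mmHg).
#' @param sample_rate ABP sampling rate in Hz.
#' @param segmentation A [segment()] result.
#' @param t0 Time of the first ABP sample (s).
#' @return A `phase_systemics` data frame (cycle, phase, mean_map,
#'   mean_etco2, mean_hr, flags) with attribute `phase_means` holding the
#'   across-cycle averages per phase.
#' @export
phase_systemics <- function(beats, breaths, abp, sample_rate, segmentation,
                            t0 = 0) {
  seg <- segmentation
  rows <- vector("list", 2L * nrow(seg))
  k <- 0L
  abp_t <- t0 + (seq_along(abp) - 1) / sample_rate
  for (i in seq_len(nrow(seg))) {
    for (phase in c("OFF", "ON")) {
      w0 <- if (phase == "OFF") seg$off_start[i] else seg$on_start[i]
      w1 <- if (phase == "OFF") seg$off_end[i] else seg$on_end[i]
      in_abp <- abp_t >= w0 & abp_t < w1
      in_b <- beats$time >= w0 & beats$time < w1
      in_r <- breaths$time >= w0 & breaths$time < w1
      hr <- beats$hr[in_b]
      flags <- character()
      mean_hr <- if (any(!is.na(hr))) mean(hr, na.rm = TRUE) else {
        flags <- c(flags, "no_beats"); NA_real_
      }
      mean_et <- if (any(in_r)) mean(breaths$etco2[in_r]) else {
        flags <- c(flags, "no_breaths"); NA_real_
      }
      mean_map <- if (any(in_abp)) mean(abp[in_abp]) else {
        flags <- c(flags, "no_abp"); NA_real_
      }
      k <- k + 1L
      rows[[k]] <- data.frame(cycle = seg$cycle[i], phase = phase,
                              mean_map = mean_map, mean_etco2 = mean_et,
                              mean_hr = mean_hr,
                              flags = paste(flags, collapse = ";"),
                              stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  pm <- stats::aggregate(out[c("mean_map", "mean_etco2", "mean_hr")],
                         by = list(phase = out$phase), FUN = mean, na.rm = TRUE)
  attr(out, "phase_means") <- pm
  class(out) <- c("phase_systemics", "data.frame")
  out
}
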