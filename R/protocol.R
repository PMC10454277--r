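#' Block-design visual stimulation protocol
#'
#' Describes the ON/OFF block design used for functional TCD assessment of
#' neurovascular coupling: repeated cycles of an eyes-closed rest phase (OFF)
#' followed by checkerboard stimulation (ON). The default protocol is
#' 10 cycles of 20 s OFF / 30 s ON with a 1 Hz pattern-reversal checkerboard
#' (the reversal rate is carried as metadata only; the stimulus itself is
#' never simulated).
#'
#' @param off_duration Rest (OFF) phase duration in seconds.
#' @param on_duration Stimulation (ON) phase duration in seconds.
#' @param n_cycles Number of ON/OFF cycles.
#' @param lead_in Baseline recorded before the first cycle, seconds. Used as
#'   the default trigger time by the simulator and pipeline.
#' @param checker_reversal_rate Checkerboard reversal rate in Hz (metadata).
#' @return An object of class `vefr_protocol`.
#' @export
#' @examples
#' stim_protocol()                    # the standard 20/30 x 10 design
#' stim_protocol(off_duration = 4, on_duration = 6, n_cycles = 3)
stim_protocol <- function(off_duration = 20, on_duration = 30, n_cycles = 10,
                          lead_in = 5, checker_reversal_rate = 1) {
  stopifnot(is.numeric(off_duration), off_duration > 0,
            is.numeric(on_duration), on_duration > 0,
            is.numeric(n_cycles), n_cycles >= 1, n_cycles == round(n_cycles),
            is.numeric(lead_in), lead_in >= 0,
            checker_reversal_rate > 0)
  structure(list(off_duration = off_duration, on_duration = on_duration,
                 n_cycles = as.integer(n_cycles), lead_in = lead_in,
                 checker_reversal_rate = checker_reversal_rate),
            class = "vefr_protocol")
}

#' @export
print.vefr_protocol <- function(x, ...) {
  cat(sprintf("fTCD stimulation protocol: %d cycles of %g s OFF / %g s ON (lead-in %g s)\n",
              x$n_cycles, x$off_duration, x$on_duration, x$lead_in))
  invisible(x)
}

#' Total duration of the protocol in seconds (excluding lead-in)
#' @param protocol A [stim_protocol()] object.
#' @return Seconds spanned by all cycles.
#' @export
protocol_span <- function(protocol) {
  protocol$n_cycles * (protocol$off_duration + protocol$on_duration)
}

#' Evoked-response kinetics
#'
#' Shape parameters of the visually evoked relative flow-velocity time
#' course: velocity starts rising about 1 s after stimulus onset, reaches a
#' maximum at 5--10 s, then relaxes to a sustained plateau; after stimulus
#' offset it returns exponentially to baseline. The curve produced from these
#' parameters is normalized so that the plateau equals 1; per-cycle response
#' amplitudes (in percent of baseline) scale it.
#'
#' @param onset_delay Seconds after ON start before the response begins.
#' @param time_to_peak Seconds after ON start at which the response peaks.
#' @param peak_amplitude Peak amplitude, percent of baseline (defines the
#'   overshoot ratio `peak_amplitude / plateau_amplitude`).
#' @param plateau_amplitude Plateau amplitude, percent of baseline.
#' @param offset_decay Time constant (s) of the return to baseline after
#'   stimulus offset.
#' @param relax_tau Time constant (s) of the relaxation from peak to plateau.
#' @param allow_inverted Permit `peak_amplitude < plateau_amplitude`
#'   (disabled by default; only useful for pathological configurations).
#' @return An object of class `vefr_kinetics`.
#' @export
response_kinetics <- function(onset_delay = 1, time_to_peak = 7,
                              peak_amplitude = 12, plateau_amplitude = 8,
                              offset_decay = 3, relax_tau = 3,
                              allow_inverted = FALSE) {
  stopifnot(onset_delay >= 0, time_to_peak >= onset_delay,
            offset_decay > 0, relax_tau > 0, plateau_amplitude >= 0)
  if (!allow_inverted && peak_amplitude < plateau_amplitude)
    stop("peak_amplitude < plateau_amplitude; set allow_inverted = TRUE if intended")
  structure(list(onset_delay = onset_delay, time_to_peak = time_to_peak,
                 peak_amplitude = peak_amplitude,
                 plateau_amplitude = plateau_amplitude,
                 offset_decay = offset_decay, relax_tau = relax_tau),
            class = "vefr_kinetics")
}

#' @export
print.vefr_kinetics <- function(x, ...) {
  cat(sprintf("Evoked-response kinetics: onset %g s, peak at %g s (overshoot x%.2f), plateau-normalized\n",
              x$onset_delay, x$time_to_peak,
              if (x$plateau_amplitude > 0) x$peak_amplitude / x$plateau_amplitude else 1))
  invisible(x)
}

# Normalized ON-phase response shape: 0 before onset, smoothstep rise to the
# overshoot ratio at time_to_peak, exponential relaxation towards 1 (the
# plateau). `u` is time since ON start. When plateau_amplitude is 0 the curve
# is peak-normalized and relaxes to 0 instead.
.on_shape <- function(u, kinetics) {
  k <- kinetics
  pk <- if (k$plateau_amplitude > 0) k$peak_amplitude / k$plateau_amplitude else 1
  tail_level <- if (k$plateau_amplitude > 0) 1 else 0
  out <- numeric(length(u))
  if (k$time_to_peak > k$onset_delay) {
    rise <- u > k$onset_delay & u <= k$time_to_peak
    x <- (u[rise] - k$onset_delay) / (k$time_to_peak - k$onset_delay)
    out[rise] <- pk * x^2 * (3 - 2 * x)
  }
  dec <- u > k$time_to_peak
  out[dec] <- tail_level + (pk - tail_level) * exp(-(u[dec] - k$time_to_peak) / k$relax_tau)
  out
}

#' Evoked-response modulation over a recording timeline
#'
#' Evaluates the relative evoked-response time course r(t) at arbitrary times
#' of a recording, given the protocol placement and per-cycle response
#' amplitudes. During each ON phase the normalized kinetic shape is scaled by
#' that cycle's amplitude; during the following OFF phase (and after the
#' protocol) the response decays exponentially back to baseline.
#'
#' @param times Times in seconds from recording start.
#' @param protocol A [stim_protocol()] object.
#' @param trigger_time Protocol start relative to recording start (s).
#' @param kinetics A [response_kinetics()] object.
#' @param amplitudes Per-cycle plateau amplitudes in percent of baseline:
#'   a vector of length `n_cycles`, or a matrix with `n_cycles` rows to
#'   evaluate several amplitude tracks (e.g. systolic and diastolic) at once.
#' @return Percent-of-baseline response: a vector, or a matrix with one
#'   column per amplitude track.
#' @export
evoked_modulation <- function(times, protocol, trigger_time, kinetics, amplitudes) {
  A <- if (is.matrix(amplitudes)) amplitudes else matrix(amplitudes, ncol = 1)
  if (nrow(A) != protocol$n_cycles)
    stop("amplitudes must have one row/value per protocol cycle")
  span <- protocol$off_duration + protocol$on_duration
  total <- protocol$n_cycles * span
  rel <- times - trigger_time

  shape <- numeric(length(times))
  amp_cycle <- integer(length(times))          # 0 = no active response

  inside <- rel >= 0 & rel < total
  cyc <- integer(length(times))
  cyc[inside] <- pmin(floor(rel[inside] / span), protocol$n_cycles - 1)
  tin <- rel - cyc * span

  on_idx <- which(inside & tin >= protocol$off_duration)
  if (length(on_idx)) {
    shape[on_idx] <- .on_shape(tin[on_idx] - protocol$off_duration, kinetics)
    amp_cycle[on_idx] <- cyc[on_idx] + 1L
  }
  r_end <- .on_shape(protocol$on_duration, kinetics)
  off_idx <- which(inside & tin < protocol$off_duration & cyc >= 1)
  if (length(off_idx)) {
    shape[off_idx] <- r_end * exp(-tin[off_idx] / kinetics$offset_decay)
    amp_cycle[off_idx] <- cyc[off_idx]
  }
  post <- which(rel >= total)
  if (length(post)) {
    shape[post] <- r_end * exp(-(rel[post] - total) / kinetics$offset_decay)
    amp_cycle[post] <- protocol$n_cycles
  }

  out <- matrix(0, length(times), ncol(A))
  act <- amp_cycle > 0L
  if (any(act)) out[act, ] <- shape[act] * A[amp_cycle[act], , drop = FALSE]
  if (ncol(out) == 1L) drop(out) else out
}
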