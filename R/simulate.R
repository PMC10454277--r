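# Synthetic-cohort generator.
#
# The generator states the world the pipeline assumes: pulsatile velocity
# envelopes at group-specific baselines, an evoked response with ~1 s onset
# and a 5-10 s peak relaxing to a plateau, 20 s OFF / 30 s ON x 10 cycles,
# systemic channels (pressure, capnogram), measurement noise, artifacts and
# an optional linear habituation slope. Two fidelities share the same
# response model: "waveform" synthesizes the sampled channels, "beat_level"
# emits per-beat series directly.

# Systolic weight of the baseline velocities, derived from the three
# programmed index responses (see ?group_params).
.pulsatility_weight <- function(gp) {
  if (!is.null(gp$pulsatility_weight)) return(gp$pulsatility_weight)
  vs <- gp$vefr_systolic[1]; vm <- gp$vefr_mean[1]; vd <- gp$vefr_diastolic[1]
  if (abs(vd - vs) < 1e-9) return(0.55)
  w <- (vd - vm) / (vd - vs)
  if (w <= 0.05 || w >= 0.95) {
    warning("programmed mean response not between systolic and diastolic; using default pulsatility")
    return(0.55)
  }
  w
}

.rtrunc <- function(n, mean, sd, lower) pmax(stats::rnorm(n, mean, sd), lower)

# Draw one subject's realization from the group distributions.
.draw_subject <- function(gp, n_cycles) {
  w <- .pulsatility_weight(gp)
  cyc <- seq_len(n_cycles) - 1
  drift <- gp$habituation_slope * cyc
  A_s <- gp$vefr_systolic[1] + drift + stats::rnorm(n_cycles, 0, gp$vefr_systolic[3])
  A_d <- gp$vefr_diastolic[1] + drift + stats::rnorm(n_cycles, 0, gp$vefr_diastolic[3])
  A_s <- A_s + stats::rnorm(1, 0, gp$vefr_systolic[2])
  A_d <- A_d + stats::rnorm(1, 0, gp$vefr_diastolic[2])
  A_m <- w * A_s + (1 - w) * A_d
  A_mca <- gp$mca_response[1] + stats::rnorm(1, 0, gp$mca_response[2]) +
    stats::rnorm(n_cycles, 0, gp$mca_response[3])
  list(
    m0_pca = .rtrunc(1, gp$baseline_pca_mean[1], gp$baseline_pca_mean[2], 10),
    m0_mca = .rtrunc(1, gp$baseline_mca_mean[1], gp$baseline_mca_mean[2], 10),
    w_pca = w, w_mca = 0.55,
    hr = min(.rtrunc(1, gp$hr[1], gp$hr[2], 45), 140),
    hr_on_increment = gp$hr_on_increment,
    map = .rtrunc(1, gp$map[1], gp$map[2], 50),
    etco2 = .rtrunc(1, gp$etco2[1], gp$etco2[2], 20),
    rr = gp$respiratory_rate,
    amplitudes = cbind(pca_s = A_s, pca_d = A_d, pca_m = A_m,
                       mca_s = A_mca, mca_d = A_mca),
    noise_sd = gp$noise_sd,
    artifact_probability = gp$artifact_probability,
    age = .rtrunc(1, gp$age[1], gp$age[2], 18),
    sex = if (stats::runif(1) < gp$sex_female_p) "F" else "M",
    bmi = .rtrunc(1, gp$bmi[1], gp$bmi[2], 15),
    smoking = stats::runif(1) < gp$smoking_p)
}

# Beat onset times over [0, duration - 0.2]: the inter-beat interval is
# 60/hr during rest and lead-in, 60/(hr + hr_on_increment) inside ON phases;
# the interval in force is the one of the phase containing the beat onset.
.beat_onsets <- function(duration, trigger, protocol, hr, hr_incr) {
  off <- protocol$off_duration; on <- protocol$on_duration
  span <- off + on; nc <- protocol$n_cycles
  on_starts <- trigger + (seq_len(nc) - 1) * span + off
  bnd <- sort(unique(pmin(c(0, on_starts, on_starts + on), duration)))
  mids <- c((bnd[-length(bnd)] + bnd[-1]) / 2, duration + 1)
  in_on <- vapply(mids, function(m) {
    rel <- m - trigger
    rel >= 0 && rel < nc * span && (rel %% span) >= off
  }, logical(1))
  rate <- ifelse(in_on, hr + hr_incr, hr)
  seg_end <- c(bnd[-1], Inf)
  limit <- duration - 0.2
  t <- 0
  out <- vector("list", 4 * nc + 8)
  k <- 0L
  while (t <= limit) {
    i <- findInterval(t, bnd)
    p <- 60 / rate[i]
    nfit <- min(floor((seg_end[i] - t - 1e-9) / p), floor((limit - t) / p))
    k <- k + 1L
    out[[k]] <- t + p * (0:nfit)
    t <- t + p * (nfit + 1)
  }
  unlist(out[seq_len(k)])
}

# Stereotyped beat pulse: half-sine-squared upstroke over `rise` (fraction of
# the beat), then a decay that is asymptotically exponential (fractional time
# constant 0.13, so the envelope returns to the diastolic floor before the
# next upstroke) but starts with zero slope and curvature matched to the
# upstroke: physiological envelope peaks are rounded, not kinked.
.beat_pulse <- function(u, rise) {
  tau <- 0.13
  p <- numeric(length(u))
  r <- u >= 0 & u <= rise
  p[r] <- sin(0.5 * pi * u[r] / rise[r])^2
  d <- u > rise
  v <- u[d] - rise[d]
  cc <- 4 * rise[d]^2 / (pi^2 * tau)        # curvature match at the peak
  p[d] <- exp(-v^2 / ((v + cc) * tau))
  p
}

# Per-beat systolic/diastolic values of one artery from the subject's truth.
.beat_values <- function(onsets, truth, protocol, kinetics, artery) {
  if (artery == "PCA") {
    m0 <- truth$m0_pca; w <- truth$w_pca
    A <- truth$amplitudes[, c("pca_s", "pca_d"), drop = FALSE]
  } else {
    m0 <- truth$m0_mca; w <- truth$w_mca
    A <- truth$amplitudes[, c("mca_s", "mca_d"), drop = FALSE]
  }
  s0 <- 3 * m0 * w
  d0 <- 1.5 * m0 * (1 - w)
  r <- evoked_modulation(onsets, protocol, protocol$lead_in, kinetics, A)
  if (!is.matrix(r)) r <- matrix(r, ncol = 2)
  list(S = s0 * (1 + r[, 1] / 100), D = d0 * (1 + r[, 2] / 100))
}

# Sample the envelope of one artery on the time grid.
.synth_envelope <- function(times, onsets, S, D, hr_fallback) {
  periods <- c(diff(onsets), 60 / hr_fallback)
  j <- findInterval(times, onsets)
  j[j < 1L] <- 1L
  u <- (times - onsets[j]) / periods[j]
  rise <- pmin(0.1 / periods[j], 0.4)
  D[j] + (S[j] - D[j]) * .beat_pulse(u, rise)
}

.draw_artifacts <- function(truth, protocol, min_dur = 1, max_dur = 3) {
  nc <- protocol$n_cycles
  span <- protocol$off_duration + protocol$on_duration
  if (truth$artifact_probability <= 0)
    return(.fast_df(list(cycle = integer(), type = character(),
                         start = numeric(), duration = numeric())))
  hit <- which(stats::runif(nc) < truth$artifact_probability)
  if (!length(hit))
    return(.fast_df(list(cycle = integer(), type = character(),
                         start = numeric(), duration = numeric())))
  type <- sample(c("dropout", "spike"), length(hit), replace = TRUE)
  dur <- stats::runif(length(hit), min_dur, max_dur)
  c0 <- protocol$lead_in + (hit - 1) * span
  start <- c0 + stats::runif(length(hit)) * (span - dur)
  .fast_df(list(cycle = hit, type = type, start = start, duration = dur))
}

# Full waveform synthesis of one subject.
.synth_recording <- function(truth, protocol, kinetics, sample_rate) {
  duration <- protocol$lead_in + protocol_span(protocol) + 5
  onsets <- .beat_onsets(duration, protocol$lead_in, protocol,
                         truth$hr, truth$hr_on_increment)
  times <- seq(0, duration, by = 1 / sample_rate)

  pca_v <- .beat_values(onsets, truth, protocol, kinetics, "PCA")
  mca_v <- .beat_values(onsets, truth, protocol, kinetics, "MCA")
  pca <- .synth_envelope(times, onsets, pca_v$S, pca_v$D, truth$hr)
  mca <- .synth_envelope(times, onsets, mca_v$S, mca_v$D, truth$hr)

  pulse <- .synth_envelope(times, onsets, rep(1, length(onsets)),
                           rep(0, length(onsets)), truth$hr)
  abp <- truth$map + 40 * (pulse - mean(pulse))
  f <- truth$rr / 60
  co2 <- truth$etco2 * (0.5 - 0.5 * cos(2 * pi * f * times))^3

  if (truth$noise_sd > 0) {
    n <- length(times)
    pca <- pca + stats::rnorm(n, 0, truth$noise_sd)
    mca <- mca + stats::rnorm(n, 0, truth$noise_sd)
    abp <- abp + stats::rnorm(n, 0, truth$noise_sd)
    co2 <- co2 + stats::rnorm(n, 0, truth$noise_sd * 0.05)
  }

  artifacts <- .draw_artifacts(truth, protocol)
  s0 <- 3 * truth$m0_pca * truth$w_pca
  d0 <- 1.5 * truth$m0_pca * (1 - truth$w_pca)
  for (a in seq_len(nrow(artifacts))) {
    idx <- which(times >= artifacts$start[a] &
                   times < artifacts$start[a] + artifacts$duration[a])
    if (!length(idx)) next
    if (artifacts$type[a] == "dropout") {
      pca[idx] <- pca[idx] * 0.02
    } else {
      pca[idx] <- pca[idx] + stats::rnorm(length(idx), 0, 3 * (s0 - d0))
    }
  }

  list(data = data.frame(time_s = times, pca_velocity = pca,
                         mca_velocity = mca, abp = abp, co2 = co2),
       sample_rate = sample_rate, trigger_time = protocol$lead_in,
       onsets = onsets, artifacts = artifacts)
}

# Beat-level synthesis of one subject (no waveforms).
.synth_beats <- function(truth, protocol, kinetics, arteries = "both") {
  duration <- protocol$lead_in + protocol_span(protocol) + 5
  onsets <- .beat_onsets(duration, protocol$lead_in, protocol,
                         truth$hr, truth$hr_on_increment)
  peak_times <- onsets + 0.1
  mk <- function(artery) {
    v <- .beat_values(onsets, truth, protocol, kinetics, artery)
    S <- v$S; D <- v$D
    if (truth$noise_sd > 0) {
      S <- S + stats::rnorm(length(S), 0, truth$noise_sd)
      D <- D + stats::rnorm(length(D), 0, truth$noise_sd)
      D <- pmin(D, S)                      # container invariant
    }
    beat_series(peak_times, S, D, artery = artery)
  }
  pca <- mk("PCA")
  mca <- if (arteries == "both") mk("MCA") else NULL

  artifacts <- .draw_artifacts(truth, protocol, min_dur = 1.5, max_dur = 3)
  artifacts$type <- rep("dropout", nrow(artifacts))     # beat deletion
  for (a in seq_len(nrow(artifacts))) {
    drop <- pca$time >= artifacts$start[a] &
      pca$time < artifacts$start[a] + artifacts$duration[a]
    if (any(drop))
      pca <- beat_series(pca$time[!drop], pca$systolic[!drop],
                         pca$diastolic[!drop], artery = "PCA")
  }
  list(pca = pca, mca = mca, artifacts = artifacts)
}

#' Simulate one subject
#'
#' Draws a subject realization from group-level distributions and
#' synthesizes either a full multi-channel recording or beat-level series.
#' Setting all SDs of a [group_params()] object to zero makes the draw
#' deterministic at the group means, which is how the calibration tests pin
#' programmed values.
#'
#' @param group_par A [group_params()] object.
#' @param protocol A [stim_protocol()].
#' @param kinetics A [response_kinetics()].
#' @param fidelity `"waveform"` or `"beat_level"`.
#' @param sample_rate Sampling rate in Hz (waveform fidelity).
#' @param subject_id,group Identifiers carried on the result.
#' @param seed Optional seed for this subject.
#' @param arteries `"both"` or `"pca"` (beat-level only).
#' @return A `vefr_subject`: `recording` (waveform fidelity: data frame of
#'   `time_s, pca_velocity, mca_velocity, abp, co2` plus sampling metadata)
#'   or `beats` (beat-level), the `truth` realization (programmed per-cycle
#'   amplitudes in `truth$amplitudes`), and the injected-`artifacts` ledger.
#' @export
simulate_subject <- function(group_par, protocol = stim_protocol(),
                             kinetics = response_kinetics(),
                             fidelity = c("waveform", "beat_level"),
                             sample_rate = 100, subject_id = "s01",
                             group = "group", seed = NULL,
                             arteries = c("both", "pca")) {
  fidelity <- match.arg(fidelity)
  arteries <- match.arg(arteries)
  if (!is.null(seed)) set.seed(seed)
  truth <- .draw_subject(group_par, protocol$n_cycles)
  out <- list(subject_id = subject_id, group = group, fidelity = fidelity,
              protocol = protocol, kinetics = kinetics, truth = truth)
  if (fidelity == "waveform") {
    syn <- .synth_recording(truth, protocol, kinetics, sample_rate)
    out$recording <- syn[c("data", "sample_rate", "trigger_time")]
    out$programmed_beats <- syn$onsets + 0.1
    out$artifacts <- syn$artifacts
  } else {
    syn <- .synth_beats(truth, protocol, kinetics, arteries)
    out$beats <- syn[c("pca", "mca")]
    out$artifacts <- syn$artifacts
  }
  class(out) <- "vefr_subject"
  out
}

#' Simulate a whole cohort
#'
#' Per-subject parameters are drawn from the configured group distributions;
#' per-cycle responses carry the within-subject SD and the linear
#' habituation slope. One root seed fully determines the cohort: per-subject
#' seeds are derived from it, so the output is reproducible byte for byte.
#'
#' @param config A [cohort_config()].
#' @return A `vefr_cohort`: `subjects` (list of `vefr_subject`), `metadata`
#'   (subject_id, group, age, sex, bmi, smoking), and `truth` — the
#'   programmed per-cycle responses in long form (subject_id, group, artery,
#'   index, cycle, programmed).
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "vefr_cohort_config"))
  set.seed(config$seed)
  n_tot <- sum(vapply(config$groups, function(g) as.numeric(g$n_subjects),
                      numeric(1)))
  seeds <- sample.int(.Machine$integer.max - 1L, n_tot)

  subjects <- vector("list", n_tot)
  meta <- vector("list", n_tot)
  truth_rows <- vector("list", n_tot)
  k <- 0L
  nc <- config$protocol$n_cycles
  for (g in names(config$groups)) {
    gp <- config$groups[[g]]
    for (i in seq_len(gp$n_subjects)) {
      k <- k + 1L
      sid <- sprintf("%s_%03d", g, i)
      s <- simulate_subject(gp, config$protocol, config$kinetics,
                            fidelity = config$fidelity,
                            sample_rate = config$sample_rate,
                            subject_id = sid, group = g, seed = seeds[k],
                            arteries = config$arteries)
      subjects[[k]] <- s
      meta[[k]] <- data.frame(subject_id = sid, group = g,
                              age = s$truth$age, sex = s$truth$sex,
                              bmi = s$truth$bmi, smoking = s$truth$smoking,
                              stringsAsFactors = FALSE)
      A <- s$truth$amplitudes
      truth_rows[[k]] <- .fast_df(list(
        subject_id = rep(sid, 6L * nc), group = rep(g, 6L * nc),
        artery = rep(c("PCA", "MCA"), each = 3 * nc),
        index = rep(rep(c("systolic", "mean", "diastolic"), each = nc), 2),
        cycle = rep(seq_len(nc), 6),
        programmed = c(A[, "pca_s"], A[, "pca_m"], A[, "pca_d"],
                       A[, "mca_s"],
                       s$truth$w_mca * A[, "mca_s"] + (1 - s$truth$w_mca) * A[, "mca_d"],
                       A[, "mca_d"])))
    }
  }
  structure(list(subjects = subjects,
                 metadata = do.call(rbind, meta),
                 truth = do.call(rbind, truth_rows),
                 config = config),
            class = "vefr_cohort")
}

#' @export
print.vefr_cohort <- function(x, ...) {
  tab <- table(x$metadata$group)
  cat(sprintf("Synthetic fTCD cohort: %d subjects (%s), %s fidelity, seed %d\n",
              nrow(x$metadata),
              paste(sprintf("%s n=%d", names(tab), tab), collapse = ", "),
              x$config$fidelity, x$config$seed))
  invisible(x)
}
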