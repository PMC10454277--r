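test_that("the response formula is exact and guarded", {
  expect_equal(compute_vefr(36.45, 32.4), 12.5, tolerance = 1e-12)
  v <- c(1, 17.3, 240)
  expect_equal(compute_vefr(v, v), c(0, 0, 0))
  # inverse: rest 32.4 with a 14.4% response implies v_stimul 37.0656
  expect_equal(compute_vefr(37.0656, 32.4), 14.4, tolerance = 1e-12)
  expect_error(compute_vefr(30, 0), "v_rest")
})

test_that("cycle_vefr equals a brute-force recomputation", {
  seg <- segment(stim_protocol(off_duration = 10, on_duration = 15,
                               n_cycles = 3), trigger_time = 2)
  for (rep_i in 1:20) {
    set.seed(100 + rep_i)
    times <- sort(runif(180, 0, 80))
    times <- times[c(TRUE, diff(times) > 0.25)]
    sys <- runif(length(times), 40, 70)
    dia <- sys * runif(length(times), 0.3, 0.8)
    b <- beat_series(times, sys, dia)
    v <- cycle_vefr(b, seg)
    for (ci in 1:3) for (idx in c("systolic", "mean", "diastolic")) {
      rest <- b[[idx]][b$time >= seg$rest_start[ci] & b$time < seg$rest_end[ci]]
      stim <- b[[idx]][b$time >= seg$stim_start[ci] & b$time < seg$stim_end[ci]]
      row <- v[v$cycle == ci & v$index == idx, ]
      if (length(rest) && length(stim)) {
        expect_true(row$included)
        expect_equal(row$response,
                     (mean(stim) - mean(rest)) / mean(rest) * 100,
                     tolerance = 1e-9)
      } else {
        expect_false(row$included)
      }
    }
  }
})

test_that("VEFR is invariant under positive rescaling of the envelope", {
  s <- simulate_subject(det_group(), fidelity = "beat_level", seed = 7)
  seg <- segment(stim_protocol(), 5)
  b <- s$beats$pca
  v1 <- cycle_vefr(b, seg)
  b2 <- beat_series(b$time, 2 * b$systolic, 2 * b$diastolic)
  v2 <- cycle_vefr(b2, seg)
  expect_equal(v2$response, v1$response, tolerance = 1e-12)
})

test_that("per-index ordering propagates to recovered responses", {
  for (seed in 1:5) {
    s <- simulate_subject(det_group(vs = 10, vm = 13, vd = 17),
                          fidelity = "beat_level", seed = seed)
    v <- cycle_vefr(s$beats$pca, segment(stim_protocol(), 5))
    sys <- v$response[v$index == "systolic"]
    dia <- v$response[v$index == "diastolic"]
    expect_true(all(dia > sys))
  }
})

test_that("subject averaging is the unweighted mean over included cycles", {
  v <- data.frame(artery = "PCA", index = "mean", cycle = 1:5,
                  v_rest = 30, v_stimul = 33,
                  response = c(10, 12, 14, 99, 99),
                  included = c(TRUE, TRUE, TRUE, FALSE, FALSE),
                  exclusion_reason = c("none", "none", "none", "dropout", "low_snr"))
  class(v) <- c("vefr_table", "data.frame")
  out <- subject_average(v)
  expect_equal(out$response, 12)
  expect_equal(out$n_cycles_included, 3L)

  v$included <- FALSE
  expect_warning(empty <- subject_average(v), "unusable")
  expect_equal(nrow(empty), 0)

  # habituation slope -0.5 from 15: mean of 15, 14.5, ..., 10.5 = 12.75
  s <- simulate_subject(det_group(vs = 15, vm = 15, vd = 15,
                                  habituation_slope = -0.5),
                        fidelity = "beat_level", seed = 1)
  v2 <- cycle_vefr(s$beats$pca, segment(stim_protocol(), 5))
  out2 <- subject_average(v2)
  expect_equal(out2$response[out2$index == "mean"], 12.75, tolerance = 0.05)
})

test_that("early-phase onset and response behave as programmed", {
  k <- response_kinetics(onset_delay = 1, time_to_peak = 7,
                         peak_amplitude = 12, plateau_amplitude = 8)
  s <- simulate_subject(det_group(vs = 8, vm = 8, vd = 8, hr_on_increment = 0),
                        kinetics = k, fidelity = "beat_level", seed = 2)
  seg <- segment(stim_protocol(), 5)
  ep <- early_phase_response(s$beats$pca, seg)
  on <- ep$onsets[is.finite(ep$onsets)]
  expect_gt(length(on), 5)
  expect_true(all(on >= 0.5 & on <= 2.0))
  expect_equal(ep$n_cycles_used, 10)

  # zero programmed response: no onset anywhere
  s0 <- simulate_subject(det_group(vs = 0, vm = 0, vd = 0),
                         fidelity = "beat_level", seed = 2)
  ep0 <- early_phase_response(s0$beats$pca, seg)
  expect_true(all(is.na(ep0$onsets)))
  expect_true(all(is.na(ep0$response)))

  # no overshoot: early phase approximately equals the plateau response
  k2 <- response_kinetics(peak_amplitude = 8, plateau_amplitude = 8)
  s2 <- simulate_subject(det_group(vs = 8, vm = 8, vd = 8, hr_on_increment = 0),
                         kinetics = k2, fidelity = "beat_level", seed = 3)
  ep2 <- early_phase_response(s2$beats$pca, seg)
  expect_equal(unname(ep2$response["mean"]), 8, tolerance = 1)
})

test_that("relative time course reproduces the plateau and baseline", {
  s <- simulate_subject(det_group(vs = 12, vm = 12, vd = 12),
                        fidelity = "beat_level", seed = 4)
  seg <- segment(stim_protocol(), 5)
  tc <- relative_time_course(s$beats$pca, seg)
  expect_equal(range(tc$time), c(-20, 30))
  base <- tc$mean[tc$time >= -5 & tc$time < 0]
  expect_true(all(abs(base) < 0.3))
  plateau <- tc$mean[tc$time >= 20 & tc$time < 30]
  expect_true(all(plateau > 11 & plateau < 13))

  # zero-response subject: flat curve
  s0 <- simulate_subject(det_group(vs = 0, vm = 0, vd = 0),
                         fidelity = "beat_level", seed = 4)
  tc0 <- relative_time_course(s0$beats$pca, seg)
  expect_true(all(abs(tc0$mean) < 1e-6))

  # single included cycle: the average equals that cycle's trace
  seg1 <- seg
  seg1$included[-3] <- FALSE
  tc1 <- relative_time_course(s$beats$pca, seg1)
  b <- s$beats$pca
  in_c <- b$time >= seg$off_start[3] & b$time < seg$on_end[3]
  vr <- mean(b$mean[b$time >= seg$rest_start[3] & b$time < seg$rest_end[3]])
  ref <- approx(b$time[in_c] - seg$on_start[3],
                (b$mean[in_c] - vr) / vr * 100, xout = tc1$time, rule = 2)$y
  expect_equal(tc1$mean, ref, tolerance = 1e-9)
})
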