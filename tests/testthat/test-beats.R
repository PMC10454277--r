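test_that("mean velocity formula and its domain", {
  expect_identical(mean_velocity(60, 30), 40)
  expect_identical(mean_velocity(50, 50), 50)
  expect_identical(mean_velocity(90, 0), 30)
  expect_error(mean_velocity(30, 60), "systolic")
  expect_error(mean_velocity(10, -1), "diastolic")
  # diastolic <= mean <= systolic, equality iff equal
  s <- runif(50, 20, 80); d <- s * runif(50, 0.2, 1)
  m <- mean_velocity(s, d)
  expect_true(all(d <= m & m <= s))
  expect_equal(m[abs(s - d) < 1e-12], s[abs(s - d) < 1e-12])
})

test_that("instantaneous heart rate comes from inter-peak intervals", {
  b <- beat_series(c(1, 1.845, 2.690), c(60, 60, 60), c(30, 30, 30))
  expect_true(is.na(b$hr[1]))
  expect_equal(round(b$hr[2], 1), 71.0)   # 60 / 0.845
  expect_error(beat_series(c(1, 1, 2), c(60, 60, 60), c(30, 30, 30)),
               "strictly increasing")
})

test_that("beat detection recovers a noiseless programmed train exactly", {
  # lead-in 5 + one 50 s cycle + 5 s tail = 60 s of pure baseline
  p1 <- stim_protocol(n_cycles = 1)
  s <- simulate_subject(det_group(vs = 0, vm = 0, vd = 0, hr = 71,
                                  hr_on_increment = 0),
                        protocol = p1, fidelity = "waveform", seed = 1)
  b <- detect_beats(s$recording$data$pca_velocity, 100)
  expect_equal(nrow(b), 71)
  expect_true(all(abs(b$hr[-1] - 71) < 0.1))

  s60 <- simulate_subject(det_group(vs = 0, vm = 0, vd = 0, hr = 60,
                                    hr_on_increment = 0),
                          protocol = p1, fidelity = "waveform", seed = 1)
  expect_equal(nrow(detect_beats(s60$recording$data$pca_velocity, 100)), 60)
})

test_that("flat signal yields an empty flagged series", {
  b <- detect_beats(rep(30, 1000), 100)
  expect_equal(nrow(b), 0)
  expect_true("no_beats" %in% attr(b, "quality"))
  expect_error(detect_beats(rep(30, 100), 100), "shorter than 5 s")
})

test_that("detection is amplitude-scale and time-shift equivariant", {
  s <- simulate_subject(det_group(), protocol = stim_protocol(n_cycles = 2),
                        fidelity = "waveform", seed = 4)
  env <- s$recording$data$pca_velocity
  b1 <- detect_beats(env, 100)
  b2 <- detect_beats(3 * env, 100)
  expect_equal(b2$time, b1$time)
  expect_equal(b2$systolic, 3 * b1$systolic, tolerance = 1e-12)
  expect_equal(b2$diastolic, 3 * b1$diastolic, tolerance = 1e-12)
  expect_equal(b2$mean, 3 * b1$mean, tolerance = 1e-12)
  b3 <- detect_beats(env, 100, t0 = 17.25)
  expect_equal(b3$time, b1$time + 17.25)
})

test_that("per-beat values match programmed values on noiseless signals", {
  s <- simulate_subject(det_group(vs = 0, vm = 0, vd = 0, hr = 65,
                                  hr_on_increment = 0),
                        protocol = stim_protocol(n_cycles = 1),
                        fidelity = "waveform", seed = 2)
  b <- detect_beats(s$recording$data$pca_velocity, 100)
  w <- s$truth$w_pca
  s0 <- 3 * s$truth$m0_pca * w
  d0 <- 1.5 * s$truth$m0_pca * (1 - w)
  expect_true(all(abs(b$systolic - s0) / s0 < 0.01))
  expect_true(all(abs(b$diastolic - d0) / d0 < 0.01))
})

test_that("breath detection reads the programmed end-tidal plateau", {
  t <- seq(0, 60, by = 0.01)
  shape <- (0.5 - 0.5 * cos(2 * pi * 0.25 * t))^3   # 15 breaths/min
  br <- detect_breaths(36 * shape, 100)
  expect_equal(nrow(br), 15)
  expect_true(all(abs(br$etco2 - 36) < 0.2))

  expect_equal(nrow(detect_breaths(rep(0, 6000), 100)), 0)

  two <- ifelse(t < 30, 36, 40) * shape
  br2 <- detect_breaths(two, 100)
  expect_equal(mean(br2$etco2[br2$time < 30]), 36, tolerance = 0.2)
  expect_equal(mean(br2$etco2[br2$time >= 30]), 40, tolerance = 0.2)
})

test_that("phase systemics average within ON/OFF windows", {
  seg <- segment(stim_protocol(n_cycles = 2), trigger_time = 0)
  b <- beat_series(seq(0.5, 99.5, by = 1), rep(60, 100), rep(30, 100))
  br <- detect_breaths(36 * (0.5 - 0.5 * cos(2 * pi * 0.25 * seq(0, 100, 0.01)))^3, 100)
  sys <- phase_systemics(b, br, abp = rep(93, 10000), sample_rate = 100,
                         segmentation = seg)
  expect_true(all(abs(sys$mean_map - 93) < 1e-9))
  expect_true(all(abs(sys$mean_etco2 - 36) < 0.2))

  # beats only in OFF windows -> ON mean HR missing with a flag
  off_only <- beat_series(c(seq(1, 19), seq(51, 69)),
                          rep(60, 38), rep(30, 38))
  sys2 <- phase_systemics(off_only, br, rep(93, 10000), 100, seg)
  on_rows <- sys2$phase == "ON"
  expect_true(all(is.na(sys2$mean_hr[on_rows])))
  expect_true(all(grepl("no_beats", sys2$flags[on_rows])))

  # programmed OFF/ON heart rates recovered from a simulated subject
  s <- simulate_subject(det_group(vs = 0, vm = 0, vd = 0, hr = 66,
                                  hr_on_increment = 1),
                        fidelity = "beat_level", seed = 1)
  seg10 <- segment(stim_protocol(), trigger_time = 5)
  sys3 <- phase_systemics(s$beats$pca, br, rep(93, 100), 100, seg10)
  pm <- attr(sys3, "phase_means")
  expect_equal(pm$mean_hr[pm$phase == "OFF"], 66, tolerance = 0.1)
  expect_equal(pm$mean_hr[pm$phase == "ON"], 67, tolerance = 0.1)
})
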