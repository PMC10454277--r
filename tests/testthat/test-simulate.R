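test_that("a fixed seed fully determines the cohort", {
  cfg <- cohort_config(groups = list(a = group_params(n_subjects = 3),
                                     b = group_params(n_subjects = 2)),
                       fidelity = "beat_level", seed = 42)
  c1 <- simulate_cohort(cfg)
  c2 <- simulate_cohort(cfg)
  expect_identical(c1$metadata, c2$metadata)
  expect_identical(c1$truth, c2$truth)
  expect_identical(c1$subjects[[4]]$beats$pca, c2$subjects[[4]]$beats$pca)

  cfgw <- cohort_config(groups = list(a = group_params(n_subjects = 1)),
                        fidelity = "waveform", seed = 42)
  expect_identical(simulate_cohort(cfgw)$subjects[[1]]$recording$data,
                   simulate_cohort(cfgw)$subjects[[1]]$recording$data)
})

test_that("plateau calibration: programmed per-index VEFR is attained", {
  s <- simulate_subject(det_group(vs = 12.9, vm = 14.4, vd = 16.7),
                        fidelity = "beat_level", seed = 1)
  v <- cycle_vefr(s$beats$pca, segment(stim_protocol(), 5))
  rec <- tapply(v$response[v$included], v$index[v$included], mean)
  expect_equal(unname(rec["systolic"]), 12.9, tolerance = 12.9 * 0.01)
  expect_equal(unname(rec["mean"]), 14.4, tolerance = 14.4 * 0.01)
  expect_equal(unname(rec["diastolic"]), 16.7, tolerance = 16.7 * 0.01)
})

test_that("beat-level and waveform fidelities agree", {
  seg <- segment(stim_protocol(), 5)
  sb <- simulate_subject(det_group(), fidelity = "beat_level", seed = 9)
  sw <- simulate_subject(det_group(), fidelity = "waveform", seed = 9)
  vb <- cycle_vefr(sb$beats$pca, seg)
  bw <- detect_beats(sw$recording$data$pca_velocity, 100)
  vw <- cycle_vefr(bw, seg)
  expect_true(all(abs(vb$response - vw$response) < 0.2))
})

test_that("habituation slope produces the programmed arithmetic sequence", {
  s <- simulate_subject(det_group(vs = 15, vm = 15, vd = 15,
                                  habituation_slope = -0.5),
                        fidelity = "beat_level", seed = 1)
  A <- s$truth$amplitudes
  expect_equal(diff(A[, "pca_s"]), rep(-0.5, 9))
  v <- cycle_vefr(s$beats$pca, segment(stim_protocol(), 5))
  r <- v$response[v$index == "mean"][order(v$cycle[v$index == "mean"])]
  expect_true(all(diff(r) < 0))
  expect_equal(diff(r), rep(-0.5, 9), tolerance = 0.05)
})

test_that("zero-response programming yields zero measured VEFR", {
  s <- simulate_subject(det_group(vs = 0, vm = 0, vd = 0, noise_sd = 1),
                        fidelity = "beat_level", seed = 6)
  v <- cycle_vefr(s$beats$pca, segment(stim_protocol(), 5))
  expect_equal(mean(v$response[v$included]), 0, tolerance = 0.5)
})

test_that("the artifact ledger records every injected cycle", {
  set.seed(1)
  n_art <- 0L
  for (seed in 1:12) {
    s <- simulate_subject(det_group(noise_sd = 1, artifact_probability = 0.3),
                          fidelity = "waveform", seed = seed)
    a <- s$artifacts
    n_art <- n_art + nrow(a)
    expect_true(all(a$cycle %in% 1:10))
    expect_true(all(a$type %in% c("dropout", "spike")))
    expect_true(all(a$duration >= 1 & a$duration <= 3))
    span <- stim_protocol()
    expect_true(all(a$start >= 5 + (a$cycle - 1) * 50 &
                      a$start + a$duration <= 5 + a$cycle * 50))
  }
  expect_gt(n_art, 10)
})

test_that("subject metadata is drawn from the configured distributions", {
  cfg <- cohort_config(groups = list(g = group_params(n_subjects = 150)),
                       fidelity = "beat_level", seed = 3, arteries = "pca")
  md <- simulate_cohort(cfg)$metadata
  expect_equal(nrow(md), 150)
  expect_equal(mean(md$age), 70.7, tolerance = 3)
  expect_lt(abs(mean(md$sex == "F") - 0.352), 0.1)   # ~2.5 binomial SE
  expect_true(is.logical(md$smoking))
})

test_that("group mean responses are recovered across a noisy cohort", {
  gp <- group_params(n_subjects = 40, vefr_systolic = c(12.9, 5, 4),
                     vefr_mean = c(14.4, 5, 4), vefr_diastolic = c(16.7, 5, 4))
  cfg <- cohort_config(groups = list(g = gp), fidelity = "beat_level",
                       seed = 8, arteries = "pca")
  co <- simulate_cohort(cfg)
  d <- cohort_vefr_long(co, index = "mean")
  rec <- mean(tapply(d$response, d$subject_id, mean))
  truth <- co$truth
  prog <- mean(tapply(truth$programmed[truth$index == "mean" & truth$artery == "PCA"],
                      truth$subject_id[truth$index == "mean" & truth$artery == "PCA"],
                      mean))
  expect_equal(rec, prog, tolerance = 0.5)
})
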