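# Deterministic single-subject group parameters: all SDs zero so the drawn
# realization equals the group means exactly.
det_group <- function(vs = 12.9, vm = 14.4, vd = 16.7, hr = 71, m0 = 32.4,
                      noise_sd = 0, hr_on_increment = 1, habituation_slope = 0,
                      within_sd = 0, artifact_probability = 0, ...) {
  group_params(n_subjects = 1,
               vefr_systolic = c(vs, 0, within_sd),
               vefr_mean = c(vm, 0, within_sd),
               vefr_diastolic = c(vd, 0, within_sd),
               mca_response = c(2.3, 0, 0),
               baseline_pca_mean = c(m0, 0), baseline_mca_mean = c(43.5, 0),
               hr = c(hr, 0), hr_on_increment = hr_on_increment,
               map = c(93, 0), etco2 = c(36, 0),
               habituation_slope = habituation_slope,
               artifact_probability = artifact_probability,
               noise_sd = noise_sd,
               age = c(70, 0), bmi = c(28, 0),
               sex_female_p = 0, smoking_p = 0, ...)
}

# Long per-cycle VEFR table (one index, PCA, included cycles) for a cohort,
# running segmentation + exclusion + cycle_vefr per subject.
cohort_vefr_long <- function(cohort, index = "mean") {
  cfg <- cohort$config
  seg0 <- segment(cfg$protocol, cfg$protocol$lead_in)
  rows <- lapply(cohort$subjects, function(s) {
    if (!is.null(s$beats)) {
      beats <- s$beats$pca
      seg <- exclude_artifact_cycles(seg0, beats)
    } else {
      df <- s$recording$data
      beats <- detect_beats(df$pca_velocity, s$recording$sample_rate)
      seg <- exclude_artifact_cycles(seg0, beats, envelope = df$pca_velocity,
                                     sample_rate = s$recording$sample_rate)
    }
    v <- cycle_vefr(beats, seg)
    ok <- v$index == index & v$included
    list(subject_id = rep(s$subject_id, sum(ok)),
         group = rep(s$group, sum(ok)),
         cycle = v$cycle[ok], response = v$response[ok])
  })
  data.frame(subject_id = unlist(lapply(rows, `[[`, "subject_id")),
             group = unlist(lapply(rows, `[[`, "group")),
             cycle = unlist(lapply(rows, `[[`, "cycle")),
             response = unlist(lapply(rows, `[[`, "response")),
             stringsAsFactors = FALSE)
}

# Monte-Carlo rejection rate of the between-group RM-ANOVA over replicate
# beat-level cohorts built from `groups`.
mc_rejection_rate <- function(groups, n_reps, seed0, index = "mean",
                              alpha = 0.05) {
  rej <- logical(n_reps)
  for (r in seq_len(n_reps)) {
    cfg <- cohort_config(groups = groups, fidelity = "beat_level",
                         seed = seed0 + r, arteries = "pca")
    d <- cohort_vefr_long(simulate_cohort(cfg), index = index)
    rej[r] <- compare_vefr_groups(d)$p < alpha
  }
  mean(rej)
}
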