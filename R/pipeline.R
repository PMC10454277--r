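#' Pipeline configuration
#'
#' Bundles every threshold and statistical option of the end-to-end run so a
#' result is reproducible from its logged configuration plus the seed.
#'
#' @param protocol A [stim_protocol()].
#' @param trigger_time Protocol start relative to recording start (s);
#'   defaults to the protocol lead-in.
#' @param hr_bounds,rr_bounds Physiological bounds for beat / breath
#'   detection (per minute).
#' @param criteria Artifact-exclusion thresholds ([exclusion_criteria()]).
#' @param welch Use Welch's t-test in the baseline table.
#' @param anova_policy Missing-cycle policy of [compare_vefr_groups()].
#' @param confounders Confounders for [habituation_regression()].
#' @param seed Seed recorded with the run.
#' @return A `vefr_pipeline_config` list.
#' @export
pipeline_config <- function(protocol = stim_protocol(),
                            trigger_time = protocol$lead_in,
                            hr_bounds = c(40, 150), rr_bounds = c(6, 30),
                            criteria = exclusion_criteria(),
                            welch = FALSE,
                            anova_policy = c("cellmeans", "complete"),
                            confounders = c("age", "bmi", "sex", "smoking"),
                            seed = 1L) {
  structure(list(protocol = protocol, trigger_time = trigger_time,
                 hr_bounds = hr_bounds, rr_bounds = rr_bounds,
                 criteria = criteria, welch = welch,
                 anova_policy = match.arg(anova_policy),
                 confounders = confounders, seed = as.integer(seed)),
            class = "vefr_pipeline_config")
}

# Extract one subject: beats, breaths, segmentation + exclusion, VEFR per
# artery, early phase, phase systemics. Works from a waveform recording
# (data frame of channels) or from beat-level series.
.extract_subject <- function(subject, config, log = NULL) {
  seg <- segment(config$protocol, config$trigger_time)
  logln <- function(...) if (!is.null(log)) cat(sprintf(...), "\n", file = log,
                                                append = TRUE)
  if (!is.null(subject$recording) || inherits(subject, "vefr_recording")) {
    rec <- if (inherits(subject, "vefr_recording")) subject else subject$recording
    df <- if (inherits(subject, "vefr_recording")) subject$data else rec$data
    sr <- rec$sample_rate
    t0 <- if (!is.null(rec$t0)) rec$t0 else df$time_s[1]
    beats_pca <- detect_beats(df$pca_velocity, sr, config$hr_bounds,
                              t0 = t0, artery = "PCA")
    beats_mca <- detect_beats(df$mca_velocity, sr, config$hr_bounds,
                              t0 = t0, artery = "MCA")
    breaths <- detect_breaths(df$co2, sr, config$rr_bounds, t0 = t0)
    seg <- exclude_artifact_cycles(seg, beats_pca, envelope = df$pca_velocity,
                                   sample_rate = sr, t0 = t0,
                                   criteria = config$criteria)
    systemics <- phase_systemics(beats_pca, breaths, df$abp, sr, seg, t0 = t0)
  } else {
    beats_pca <- subject$beats$pca
    beats_mca <- subject$beats$mca
    breaths <- NULL
    seg <- exclude_artifact_cycles(seg, beats_pca, criteria = config$criteria)
    systemics <- NULL
  }
  for (i in which(!seg$included))
    logln("subject %s: cycle %d excluded (%s)",
          subject$subject_id %||% "?", seg$cycle[i], seg$exclusion_reason[i])

  vefr <- cycle_vefr(beats_pca, seg)
  if (!is.null(beats_mca)) vefr <- rbind(vefr, cycle_vefr(beats_mca, seg))
  usable <- any(vefr$included)
  if (!usable) logln("subject %s: unusable (no included cycles)",
                     subject$subject_id %||% "?")
  early <- if (usable) tryCatch(early_phase_response(beats_pca, seg),
                                error = function(e) NULL) else NULL
  list(beats = beats_pca, beats_mca = beats_mca, breaths = breaths,
       segmentation = seg, vefr = vefr,
       subject_mean = if (usable) subject_average(vefr) else NULL,
       early = early, systemics = systemics, usable = usable)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the full analysis pipeline on a cohort
#'
#' Executes, per subject: beat and breath extraction, protocol segmentation
#' with artifact-cycle exclusion, per-cycle VEFR for PCA and MCA, the
#' early-phase response and phase-wise systemic means; then the cohort
#' statistics: baseline table, per-index repeated-measures group comparison
#' and habituation regression. Subjects whose extraction fails or who keep
#' no cycles are skipped and logged; the run fails only on an empty cohort.
#'
#' @param cohort A [simulate_cohort()] result, or a directory path holding
#'   per-subject recordings plus `metadata.csv` (see [write_cohort()]).
#' @param config A [pipeline_config()].
#' @param out_dir Optional output directory for tidy result tables and the
#'   run log.
#' @return A list: `vefr` (per-cycle long table across subjects),
#'   `subjects` (per-subject mean responses), `baseline`, `anova` (per PCA
#'   index), `regression` (per PCA index), `metadata`, `excluded_subjects`.
#' @export
run_pipeline <- function(cohort, config = pipeline_config(), out_dir = NULL) {
  log <- NULL
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    log <- file.path(out_dir, "run_log.txt")
    cat(sprintf("pipeline run, seed %d\n", config$seed), file = log)
  }
  if (is.character(cohort)) {
    dir <- cohort
    if (!file.exists(file.path(dir, "metadata.csv")))
      stop("empty cohort: no metadata.csv in ", dir)
    meta <- read_metadata(file.path(dir, "metadata.csv"))
    files <- file.path(dir, paste0(meta$subject_id, ".csv"))
    subjects <- lapply(seq_len(nrow(meta)), function(i) {
      r <- read_recording(files[i], subject_id = meta$subject_id[i])
      list(subject_id = meta$subject_id[i], group = meta$group[i],
           recording = r)
    })
  } else {
    stopifnot(inherits(cohort, "vefr_cohort"))
    subjects <- cohort$subjects
    meta <- cohort$metadata
  }
  if (!length(subjects)) stop("empty cohort")

  vefr_rows <- list(); subj_rows <- list(); excluded <- character()
  for (s in subjects) {
    ex <- tryCatch(.extract_subject(s, config, log = log),
                   error = function(e) {
                     if (!is.null(log))
                       cat(sprintf("subject %s: extraction failed (%s)\n",
                                   s$subject_id, conditionMessage(e)),
                           file = log, append = TRUE)
                     NULL
                   })
    if (is.null(ex) || !ex$usable) {
      excluded <- c(excluded, s$subject_id)
      next
    }
    v <- ex$vefr
    v$subject_id <- s$subject_id
    v$group <- s$group
    vefr_rows[[s$subject_id]] <- v
    sm <- ex$subject_mean
    sm$subject_id <- s$subject_id
    sm$group <- s$group
    subj_rows[[s$subject_id]] <- sm
  }
  if (!length(vefr_rows)) stop("no usable subjects in cohort")
  vefr_all <- do.call(rbind, vefr_rows)
  rownames(vefr_all) <- NULL
  subj_all <- do.call(rbind, subj_rows)
  rownames(subj_all) <- NULL

  two_groups <- length(unique(meta$group)) == 2 &&
    min(table(meta$group[meta$subject_id %in% subj_all$subject_id])) >= 2
  baseline <- if (two_groups)
    summarize_baseline(meta[meta$subject_id %in% subj_all$subject_id,
                            setdiff(names(meta), "subject_id"), drop = FALSE],
                       welch = config$welch) else NULL

  anova <- list(); regression <- list()
  if (two_groups) {
    for (idx in c("systolic", "mean", "diastolic")) {
      d <- vefr_all[vefr_all$artery == "PCA" & vefr_all$index == idx &
                      vefr_all$included,
                    c("subject_id", "group", "cycle", "response")]
      anova[[idx]] <- compare_vefr_groups(d, policy = config$anova_policy)
      regression[[idx]] <- tryCatch(
        habituation_regression(d, metadata = meta,
                               confounders = intersect(config$confounders,
                                                       names(meta))),
        error = function(e) NULL)
    }
  }

  out <- list(vefr = vefr_all, subjects = subj_all, baseline = baseline,
              anova = anova, regression = regression, metadata = meta,
              excluded_subjects = excluded, config = config)
  if (!is.null(out_dir)) {
    data.table::fwrite(vefr_all, file.path(out_dir, "vefr_cycles.csv"))
    data.table::fwrite(subj_all, file.path(out_dir, "vefr_subjects.csv"))
    if (!is.null(baseline))
      data.table::fwrite(baseline, file.path(out_dir, "baseline_table.csv"))
    if (length(anova)) {
      at <- do.call(rbind, lapply(names(anova), function(i)
        data.frame(index = i, F = anova[[i]]$F, p = anova[[i]]$p,
                   df1 = anova[[i]]$df[1], df2 = anova[[i]]$df[2],
                   stringsAsFactors = FALSE)))
      data.table::fwrite(at, file.path(out_dir, "group_anova.csv"))
    }
    if (length(regression)) {
      rt <- do.call(rbind, lapply(names(regression), function(i)
        if (!is.null(regression[[i]]))
          cbind(index = i, regression[[i]]$coefficients)))
      if (!is.null(rt)) data.table::fwrite(rt, file.path(out_dir, "habituation_regression.csv"))
    }
  }
  out
}
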