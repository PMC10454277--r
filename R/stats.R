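#' Two-sample t-test from summary statistics
#'
#' Pooled-variance (Student) or Welch t-test computed from group means, SDs
#' and sizes only — handy for checking published baseline tables.
#'
#' @param m1,s1,n1 Mean, SD and size of group 1.
#' @param m2,s2,n2 Mean, SD and size of group 2.
#' @param welch Use the Welch (unequal-variance) form.
#' @return List with `t`, `df`, `p`.
#' @export
t_test_summary <- function(m1, s1, n1, m2, s2, n2, welch = FALSE) {
  if (welch) {
    se2 <- s1^2 / n1 + s2^2 / n2
    t <- (m1 - m2) / sqrt(se2)
    df <- se2^2 / ((s1^2 / n1)^2 / (n1 - 1) + (s2^2 / n2)^2 / (n2 - 1))
  } else {
    sp2 <- ((n1 - 1) * s1^2 + (n2 - 1) * s2^2) / (n1 + n2 - 2)
    t <- (m1 - m2) / sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- n1 + n2 - 2
  }
  list(t = t, df = df, p = 2 * stats::pt(-abs(t), df))
}

#' Baseline comparison table
#'
#' Mirrors the usual "Table 1": numeric variables compared between the two
#' groups by Student's t-test (pooled variance by default, Welch optional),
#' categorical variables by Pearson's chi-squared test without continuity
#' correction. Missing values are dropped per variable with the retained
#' counts reported. Variables constant in both groups are skipped with a
#' note.
#'
#' @param metadata Data frame with a group column and subject variables.
#' @param group_col Name of the grouping column (must have two levels).
#' @param welch Use Welch's t-test for numeric variables.
#' @return Data frame with one row per variable: per-group summaries
#'   (`mean (sd)` or `count (%)`), test name, statistic, p-value, n used.
#' @export
summarize_baseline <- function(metadata, group_col = "group", welch = FALSE) {
  g <- factor(metadata[[group_col]])
  if (nlevels(g) != 2) stop("exactly two groups required")
  if (min(table(g)) < 2) stop("each group needs >= 2 subjects")
  vars <- setdiff(names(metadata), c(group_col, "subject_id"))
  rows <- list()
  for (v in vars) {
    x <- metadata[[v]]
    ok <- !is.na(x) & !is.na(g)
    xv <- x[ok]; gv <- droplevels(g[ok])
    if (nlevels(gv) < 2) next
    fmt <- function(s) s
    if (is.numeric(x)) {
      m <- tapply(xv, gv, mean); s <- tapply(xv, gv, stats::sd)
      if (all(s == 0, na.rm = TRUE) || length(unique(xv)) == 1) {
        rows[[v]] <- data.frame(variable = v, type = "numeric",
                                group1 = sprintf("%.2f (0)", m[1]),
                                group2 = sprintf("%.2f (0)", m[2]),
                                test = "none", statistic = NA_real_,
                                p = NA_real_, n = length(xv),
                                note = "constant", stringsAsFactors = FALSE)
        next
      }
      tt <- t_test_summary(m[1], s[1], sum(gv == levels(gv)[1]),
                           m[2], s[2], sum(gv == levels(gv)[2]), welch = welch)
      rows[[v]] <- data.frame(variable = v, type = "numeric",
                              group1 = sprintf("%.2f (%.2f)", m[1], s[1]),
                              group2 = sprintf("%.2f (%.2f)", m[2], s[2]),
                              test = if (welch) "Welch t" else "Student t",
                              statistic = unname(tt$t), p = unname(tt$p),
                              n = length(xv), note = "", stringsAsFactors = FALSE)
    } else {
      xv <- factor(xv)
      if (nlevels(xv) < 2) {
        rows[[v]] <- data.frame(variable = v, type = "categorical",
                                group1 = "", group2 = "", test = "none",
                                statistic = NA_real_, p = NA_real_,
                                n = length(xv), note = "constant",
                                stringsAsFactors = FALSE)
        next
      }
      tab <- table(gv, xv)
      cs <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
      lv <- levels(xv)[nlevels(xv)]       # report the last level's share
      cnt <- tab[, lv]
      tot <- rowSums(tab)
      rows[[v]] <- data.frame(variable = v, type = "categorical",
                              group1 = sprintf("%d (%.1f%%)", cnt[1], 100 * cnt[1] / tot[1]),
                              group2 = sprintf("%d (%.1f%%)", cnt[2], 100 * cnt[2] / tot[2]),
                              test = "Pearson chi-squared",
                              statistic = unname(cs$statistic),
                              p = unname(cs$p.value),
                              n = length(xv), note = "", stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Shapiro-Wilk normality screen
#'
#' @param x Data frame or named list of numeric vectors.
#' @param alpha Flagging level.
#' @return Data frame: variable, n, W, p, normal flag, note (variables with
#'   n outside [3, 5000] or constant are skipped with a note).
#' @export
shapiro_wilk_screen <- function(x, alpha = 0.05) {
  rows <- lapply(names(x), function(v) {
    xx <- x[[v]][!is.na(x[[v]])]
    if (!is.numeric(xx))
      return(NULL)
    if (length(xx) < 3 || length(xx) > 5000)
      return(data.frame(variable = v, n = length(xx), W = NA_real_,
                        p = NA_real_, normal = NA, note = "n outside [3, 5000]",
                        stringsAsFactors = FALSE))
    if (length(unique(xx)) == 1)
      return(data.frame(variable = v, n = length(xx), W = NA_real_,
                        p = NA_real_, normal = NA, note = "constant",
                        stringsAsFactors = FALSE))
    sw <- stats::shapiro.test(xx)
    data.frame(variable = v, n = length(xx), W = unname(sw$statistic),
               p = sw$p.value, normal = sw$p.value >= alpha, note = "",
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Mixed-design (repeated-measures) ANOVA for group comparison of VEFR
#'
#' Group is the between-subject factor and cycle (1..n) the within-subject
#' factor on per-cycle responses. The headline result is the between-group
#' main effect: F = MS(group) / MS(subjects within group), computed from
#' subject-level means. With the default `"cellmeans"` policy, subjects
#' missing cycles (artifact exclusions) contribute the mean of their
#' available cycles; `"complete"` keeps complete cases only. Within-subject
#' effects (cycle, group x cycle) and the Greenhouse-Geisser epsilon are
#' reported when the retained data are balanced over a common cycle set.
#'
#' @param data Data frame with columns `subject_id`, `group`, `cycle`,
#'   `response` (one velocity index, included cycles only).
#' @param policy Missing-cycle policy, `"cellmeans"` or `"complete"`.
#' @return List: `F`, `p`, `df` (between effect), `group_means`,
#'   `group_sds`, `n`, and `within` (cycle / interaction table with
#'   Greenhouse-Geisser epsilon, or NULL when unbalanced).
#' @export
compare_vefr_groups <- function(data, policy = c("cellmeans", "complete")) {
  policy <- match.arg(policy)
  stopifnot(all(c("subject_id", "group", "cycle", "response") %in% names(data)))
  data <- data[is.finite(data$response), , drop = FALSE]
  cycles <- sort(unique(data$cycle))
  if (policy == "complete") {
    cnt <- tapply(data$cycle, data$subject_id, function(x) length(unique(x)))
    keep <- names(cnt)[cnt == length(cycles)]
    data <- data[data$subject_id %in% keep, , drop = FALSE]
  }
  sid <- factor(data$subject_id)
  smean <- tapply(data$response, sid, mean)
  sgroup <- factor(tapply(as.character(data$group), sid, `[`, 1))
  if (nlevels(sgroup) < 2) stop("two groups required")
  if (min(table(sgroup)) < 2) stop("each group needs >= 2 subjects with data")

  N <- length(smean); G <- nlevels(sgroup)
  gm <- tapply(smean, sgroup, mean)
  gs <- tapply(smean, sgroup, stats::sd)
  grand <- mean(smean)
  ssg <- sum(table(sgroup) * (gm - grand)^2)
  sse <- sum((smean - gm[sgroup])^2)
  Fg <- (ssg / (G - 1)) / (sse / (N - G))
  pg <- stats::pf(Fg, G - 1, N - G, lower.tail = FALSE)

  # Within-subject part on a balanced common cycle set, if available.
  within <- NULL
  tabsc <- table(sid, data$cycle)
  if (all(tabsc %in% c(0L, 1L))) {
    common <- cycles[colSums(tabsc == 1L) == N]
    if (length(common) >= 2) {
      d2 <- data[data$cycle %in% common, , drop = FALSE]
      Y <- matrix(NA_real_, N, length(common),
                  dimnames = list(levels(sid), common))
      Y[cbind(match(d2$subject_id, levels(sid)), match(d2$cycle, common))] <-
        d2$response
      if (!anyNA(Y)) {
        k <- ncol(Y)
        ybar <- mean(Y)
        subj_m <- rowMeans(Y); cyc_m <- colMeans(Y)
        grp <- sgroup
        grp_m <- tapply(subj_m, grp, mean)
        gc_m <- apply(Y, 2, function(col) tapply(col, grp, mean))  # G x k
        ss_tot <- sum((Y - ybar)^2)
        ss_subj <- k * sum((subj_m - ybar)^2)
        ss_grp <- k * sum(table(grp) * (grp_m - ybar)^2)
        ss_sw <- ss_subj - ss_grp
        ss_cyc <- N * sum((cyc_m - ybar)^2)
        ng <- as.vector(table(grp))
        ss_gc <- 0   # interaction SS from cell means
        for (gi in seq_len(G)) for (ci in seq_len(k))
          ss_gc <- ss_gc + ng[gi] * (gc_m[gi, ci] - grp_m[gi] - cyc_m[ci] + ybar)^2
        ss_err <- ss_tot - ss_subj - ss_cyc - ss_gc
        df_cyc <- k - 1; df_gc <- (G - 1) * (k - 1); df_err <- (N - G) * (k - 1)
        F_cyc <- (ss_cyc / df_cyc) / (ss_err / df_err)
        F_gc <- (ss_gc / df_gc) / (ss_err / df_err)
        # Greenhouse-Geisser epsilon from the group-mean-centred covariance
        R <- Y
        for (gi in seq_len(G)) R[grp == levels(grp)[gi], ] <-
          sweep(Y[grp == levels(grp)[gi], , drop = FALSE], 2, gc_m[gi, ])
        S <- stats::cov(R)
        C <- diag(k) - 1 / k
        CSC <- C %*% S %*% C
        eps <- sum(diag(CSC))^2 / ((k - 1) * sum(CSC * CSC))
        within <- data.frame(
          effect = c("cycle", "group:cycle"),
          df1 = c(df_cyc, df_gc), df2 = df_err,
          F = c(F_cyc, F_gc),
          p = stats::pf(c(F_cyc, F_gc), c(df_cyc, df_gc), df_err, lower.tail = FALSE),
          p_gg = stats::pf(c(F_cyc, F_gc), c(df_cyc, df_gc) * eps, df_err * eps,
                           lower.tail = FALSE),
          stringsAsFactors = FALSE)
        attr(within, "gg_epsilon") <- eps
      }
    }
  }

  list(F = unname(Fg), p = unname(pg), df = c(G - 1, N - G),
       group_means = gm, group_sds = gs, n = table(sgroup),
       policy = policy, within = within)
}

#' Habituation regression
#'
#' Ordinary least squares of per-cycle VEFR on cycle number, group, and
#' optional subject-level confounders. The cycle-number coefficient is the
#' habituation test: a negative significant slope indicates declining
#' responses over repeated stimulation.
#'
#' @param data Data frame with `subject_id`, `group`, `cycle`, `response`
#'   (one index, included cycles only).
#' @param metadata Optional subject metadata merged on `subject_id`.
#' @param confounders Confounder column names (in `metadata`); collinear
#'   terms are dropped with a warning.
#' @return List: `coefficients` (term, estimate, se, t, p), `model` (the
#'   `lm` fit), `n`.
#' @export
habituation_regression <- function(data, metadata = NULL,
                                   confounders = character()) {
  stopifnot(all(c("subject_id", "group", "cycle", "response") %in% names(data)))
  d <- data[is.finite(data$response), , drop = FALSE]
  if (nrow(d) < 10) stop("need >= 10 cycle-level observations")
  if (!is.null(metadata) && length(confounders))
    d <- merge(d, metadata[, c("subject_id", confounders), drop = FALSE],
               by = "subject_id")
  terms <- c("cycle", "group", confounders)
  fml <- stats::as.formula(paste("response ~", paste(terms, collapse = " + ")))
  fit <- stats::lm(fml, data = d)
  cf <- stats::coef(fit)
  if (anyNA(cf)) {
    warning("collinear term(s) dropped: ",
            paste(names(cf)[is.na(cf)], collapse = ", "))
  }
  sm <- summary(fit)$coefficients
  list(coefficients = data.frame(term = rownames(sm), estimate = sm[, 1],
                                 se = sm[, 2], t = sm[, 3], p = sm[, 4],
                                 row.names = NULL, stringsAsFactors = FALSE),
       model = fit, n = nrow(d))
}

#' Sample size for a two-group comparison
#'
#' Smallest integer per-group size whose two-sample t-test power reaches the
#' target, found by iteration from the normal-approximation start
#' `n = 2 ((z_{1-alpha/side} + z_{power}) sd / delta)^2`.
#'
#' @param delta Detectable group difference (same units as `sd`).
#' @param sd Common SD.
#' @param power Target power, in (0, 1).
#' @param alpha Significance level, in (0, 1).
#' @param sided 1 or 2.
#' @return List: `n` per group and `achieved_power`.
#' @export
#' @examples
#' sample_size_two_groups(3, 5, 0.80, 0.05, sided = 2)
sample_size_two_groups <- function(delta, sd, power = 0.80, alpha = 0.05,
                                   sided = 2) {
  stopifnot(delta > 0, sd > 0, power > 0, power < 1, alpha > 0, alpha < 1,
            sided %in% c(1, 2))
  pw <- function(n) {
    df <- 2 * n - 2
    ncp <- delta / (sd * sqrt(2 / n))
    if (sided == 2) {
      tc <- stats::qt(1 - alpha / 2, df)
      1 - stats::pt(tc, df, ncp) + stats::pt(-tc, df, ncp)
    } else {
      1 - stats::pt(stats::qt(1 - alpha, df), df, ncp)
    }
  }
  z <- stats::qnorm(1 - alpha / sided) + stats::qnorm(power)
  n <- max(2L, as.integer(ceiling(2 * (z * sd / delta)^2)))
  guard <- 0L
  while (pw(n) < power) {
    n <- n + 1L
    guard <- guard + 1L
    if (guard > 1e6) stop("target power unreachable")
  }
  while (n > 2L && pw(n - 1L) >= power) n <- n - 1L
  list(n = n, achieved_power = pw(n))
}
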