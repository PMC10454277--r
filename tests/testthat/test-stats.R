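test_that("sample size iteration is exact and monotone", {
  out <- sample_size_two_groups(3, 5, 0.80, 0.05, sided = 2)
  expect_equal(out$n, 45)               # normal approx 43.6; exact t needs 45
  expect_gte(out$achieved_power, 0.80)
  out1 <- sample_size_two_groups(3, 5, 0.80, 0.05, sided = 1)
  expect_equal(out1$n, 36)
  expect_equal(sample_size_two_groups(1e6, 5, 0.80, 0.05)$n, 2)

  # monotone in delta, sd and power
  n_delta <- vapply(c(2, 3, 4, 6), function(d)
    sample_size_two_groups(d, 5, 0.8, 0.05)$n, numeric(1))
  expect_true(all(diff(n_delta) <= 0))
  n_sd <- vapply(c(3, 5, 8), function(s)
    sample_size_two_groups(3, s, 0.8, 0.05)$n, numeric(1))
  expect_true(all(diff(n_sd) >= 0))
  n_pow <- vapply(c(0.5, 0.8, 0.9, 0.99), function(p)
    sample_size_two_groups(3, 5, p, 0.05)$n, numeric(1))
  expect_true(all(diff(n_pow) >= 0))
})

test_that("baseline table reproduces published-style comparisons", {
  md <- data.frame(
    group = rep(c("stenosis", "control"), c(54, 43)),
    sex = c(rep(c("F", "M"), c(19, 35)), rep(c("F", "M"), c(13, 30))),
    stringsAsFactors = FALSE)
  out <- summarize_baseline(md)
  # Pearson chi-squared without continuity correction on the 2x2 table
  expect_equal(out$statistic[out$variable == "sex"], 0.2656, tolerance = 1e-3)
  oracle <- suppressWarnings(
    chisq.test(table(md$group, md$sex), correct = FALSE))
  expect_equal(out$statistic[out$variable == "sex"],
               unname(oracle$statistic), tolerance = 1e-12)
  expect_equal(out$p[out$variable == "sex"], oracle$p.value, tolerance = 1e-12)

  # summary-statistic t-test: published age summaries are indistinguishable
  tt <- t_test_summary(70.7, 9.8, 54, 70.6, 10.9, 43)
  expect_lt(abs(tt$t), 0.1)
  # and agrees with stats::t.test on raw data
  set.seed(1)
  x <- rnorm(20, 10, 2); y <- rnorm(25, 11, 2)
  ref <- t.test(x, y, var.equal = TRUE)
  mine <- t_test_summary(mean(x), sd(x), 20, mean(y), sd(y), 25)
  expect_equal(mine$t, unname(ref$statistic), tolerance = 1e-10)
  expect_equal(mine$p, ref$p.value, tolerance = 1e-10)
})

test_that("identical groups give t = 0, p = 1; constants are skipped", {
  md <- data.frame(group = rep(c("a", "b"), each = 10),
                   age = rep(rnorm(10, 70, 5), 2),
                   fixed = 3,
                   cat = rep("x", 20), stringsAsFactors = FALSE)
  out <- summarize_baseline(md)
  expect_equal(out$statistic[out$variable == "age"], 0, tolerance = 1e-12)
  expect_equal(out$p[out$variable == "age"], 1, tolerance = 1e-12)
  expect_equal(out$note[out$variable == "fixed"], "constant")
  expect_equal(out$note[out$variable == "cat"], "constant")
})

test_that("normality screen flags skew and skips degenerate input", {
  set.seed(7)
  hits <- vapply(1:30, function(i)
    shapiro_wilk_screen(list(x = rexp(100)))$p < 0.05, logical(1))
  expect_gte(mean(hits), 0.95)
  out <- shapiro_wilk_screen(list(c2 = rep(1, 10), short = c(1, 2)))
  expect_equal(out$note, c("constant", "n outside [3, 5000]"))
})

test_that("between-group F agrees with the aov oracle", {
  set.seed(21)
  d <- expand.grid(subject_id = sprintf("s%02d", 1:12), cycle = 1:5)
  d$group <- ifelse(as.integer(sub("s", "", d$subject_id)) <= 6, "a", "b")
  d$response <- rnorm(nrow(d), 10, 3) + 2 * (d$group == "b") +
    rep(rnorm(12, 0, 2), 5)
  mine <- compare_vefr_groups(d)
  fit <- summary(aov(response ~ group * factor(cycle) +
                       Error(factor(subject_id)), data = d))
  ref <- fit[["Error: factor(subject_id)"]][[1]]
  expect_equal(mine$F, ref[["F value"]][1], tolerance = 1e-9)
  expect_equal(mine$p, ref[["Pr(>F)"]][1], tolerance = 1e-9)
  within <- fit[["Error: Within"]][[1]]
  expect_equal(mine$within$F[mine$within$effect == "cycle"],
               within[["F value"]][1], tolerance = 1e-9)
  expect_equal(mine$within$F[mine$within$effect == "group:cycle"],
               within[["F value"]][2], tolerance = 1e-9)

  # invariant to adding a constant
  d2 <- d; d2$response <- d2$response + 1000
  expect_equal(compare_vefr_groups(d2)$F, mine$F, tolerance = 1e-8)
})

test_that("one cycle per subject degenerates to one-way ANOVA", {
  set.seed(5)
  d <- data.frame(subject_id = sprintf("s%d", 1:6),
                  group = rep(c("a", "b"), each = 3),
                  cycle = 1L,
                  response = c(10.2, 11.5, 9.8, 13.1, 12.4, 14.0))
  mine <- compare_vefr_groups(d)
  # brute-force sums of squares
  gm <- tapply(d$response, d$group, mean); grand <- mean(d$response)
  ssb <- sum(3 * (gm - grand)^2)
  ssw <- sum((d$response - gm[d$group])^2)
  Fref <- (ssb / 1) / (ssw / 4)
  expect_equal(mine$F, Fref, tolerance = 1e-9)
  expect_equal(mine$df, c(1, 4))
})

test_that("missing-cycle policies differ as documented", {
  set.seed(31)
  d <- expand.grid(subject_id = sprintf("s%02d", 1:10), cycle = 1:4)
  d$group <- rep(c("a", "b"), 20)
  d$response <- rnorm(40, 12, 3)
  d_miss <- d[-c(3, 17), ]               # two subjects lose a cycle
  cm <- compare_vefr_groups(d_miss, policy = "cellmeans")
  cc <- compare_vefr_groups(d_miss, policy = "complete")
  expect_equal(sum(cm$n), 10)
  expect_equal(sum(cc$n), 8)
})

test_that("habituation regression recovers slope and group offset", {
  set.seed(13)
  n1 <- 30; n2 <- 30
  d <- expand.grid(subject_id = sprintf("s%02d", 1:(n1 + n2)), cycle = 1:10)
  d$group <- ifelse(as.integer(sub("s", "", d$subject_id)) <= n1, "ctl", "sten")
  d$response <- 12 - 0.5 * d$cycle + 2.4 * (d$group == "sten") +
    rnorm(nrow(d), 0, 0.5)
  fit <- habituation_regression(d)
  cf <- fit$coefficients
  expect_equal(cf$estimate[cf$term == "cycle"], -0.5, tolerance = 0.05)
  expect_equal(cf$estimate[cf$term == "groupsten"], 2.4, tolerance = 0.2)

  md <- data.frame(subject_id = unique(d$subject_id))
  md$age <- rnorm(nrow(md), 70, 9)
  md$age2 <- md$age * 2                  # perfectly collinear
  expect_warning(habituation_regression(d, md, c("age", "age2")),
                 "collinear")
  expect_error(habituation_regression(d[1:5, ]), ">= 10")
})
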