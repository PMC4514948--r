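test_that("ICC(2,1) matches an independent two-way ANOVA on a worked 6x2 table", {
  m <- cbind(c(9, 6, 8, 7, 10, 6), c(2, 1, 4, 1, 5, 2))
  fit <- icc_2_1(m)
  # independent decomposition via aov()
  df <- data.frame(y = as.vector(m), s = factor(rep(1:6, 2)),
                   r = factor(rep(1:2, each = 6)))
  ms <- summary(stats::aov(y ~ s + r, data = df))[[1]][["Mean Sq"]]
  expect_equal(unname(fit$ms), ms, tolerance = 1e-12)
  expect_equal(fit$icc, 0.12565445026178, tolerance = 1e-10)
  expect_true(fit$ci[1] <= fit$icc && fit$icc <= fit$ci[2])
  td <- tidy(fit)
  expect_equal(td$estimate, fit$icc)
})

test_that("ICC degenerate and error cases behave as specified", {
  perfect <- matrix(rep(c(3, 5, 9, 1), 3), ncol = 3)
  f <- icc_2_1(perfect)
  expect_equal(f$icc, 1)
  expect_equal(f$ci, c(1, 1))
  expect_error(icc_2_1(matrix(2, 4, 3)), "zero total variance")
  expect_error(icc_2_1(matrix(1:3, 1, 3)), "at least 2")
})

test_that("ICC approaches the analytic variance ratio on a large simulated table", {
  tab <- simulate_rater_table(rater_sim_spec(2000, 3, subject_sd = 1,
                                             rater_sd = 0.3, error_sd = 0.4,
                                             seed = 1))
  fit <- icc_2_1(tab)
  expect_lt(abs(fit$icc - 1 / (1 + 0.09 + 0.16)), 0.02)
  expect_lt(fit$ci[1], fit$icc)
  expect_gt(fit$ci[2], fit$icc)
})

test_that("ICC is invariant under common affine rescaling", {
  tab <- simulate_rater_table(rater_sim_spec(40, 3, seed = 9))
  m <- rater_matrix(tab)
  expect_equal(icc_2_1(25.4 * m + 3)$icc, icc_2_1(m)$icc, tolerance = 1e-12)
})

test_that("RMS-SD: worked example, degenerate case, units, and consistency", {
  expect_equal(rms_sd(rbind(c(0, 3 * sqrt(2)), c(0, 4 * sqrt(2))))[1],
               sqrt((9 + 16) / 2), tolerance = 1e-9)
  expect_equal(rms_sd(matrix(5, 4, 3))[1], 0)
  m <- matrix(stats::rnorm(60), 20, 3)
  expect_equal(rms_sd(10 * m)[1], 10 * rms_sd(m)[1], tolerance = 1e-12)
  expect_error(rms_sd(matrix(1, 5, 1)), "at least 2 repeats")
  # estimator consistency: pure measurement error of known scale
  tab <- simulate_rater_table(rater_sim_spec(2000, 3, subject_sd = 1,
                                             rater_sd = 0, error_sd = 0.2,
                                             seed = 3))
  expect_lt(abs(rms_sd(rater_matrix(tab))[1] - 0.2) / 0.2, 0.10)
})

test_that("paired t: closed forms, zero-variance reporting, and t.test agreement", {
  expect_equal(paired_t(c(1, 2, 3), c(1, 2, 3))[c("t", "p")], list(t = 0, p = 1))
  # constant difference 1.0 with sd exactly 1.0, n = 100 -> t = 10
  set.seed(2)
  d <- as.vector(scale(stats::rnorm(100))) + 1
  ft <- paired_t(d, rep(0, 100))
  expect_equal(ft$t, 10, tolerance = 1e-12)
  set.seed(7)
  x <- stats::rnorm(30); y <- stats::rnorm(30)
  tt <- stats::t.test(x, y, paired = TRUE)
  ours <- paired_t(x, y)
  expect_equal(ours$t, unname(tt$statistic), tolerance = 1e-12)
  expect_equal(ours$p, tt$p.value, tolerance = 1e-12)
  off <- paired_t(c(2, 3, 4), c(1, 2, 3))
  expect_true(off$exact)
  expect_equal(off$p, 0)
})

test_that("ANCOVA matches the lm oracle on a printed 8-row toy table", {
  ch <- data.frame(value = c(5.2, 5.8, 5.5, 6.1, 6.9, 7.4, 7.2, 7.8),
                   sex = c("F", "F", "F", "F", "M", "M", "M", "M"),
                   height = c(1.58, 1.62, 1.60, 1.66, 1.70, 1.76, 1.74, 1.80))
  fit <- ancova_sex(ch)
  expect_equal(fit$F, 8.1587956200563, tolerance = 1e-8)
  expect_equal(fit$p, 0.0355577030449152, tolerance = 1e-8)
  expect_equal(fit$sex_effect, 0.340517241379311, tolerance = 1e-8)
  expect_equal(fit$adjusted_means$adjusted_mean,
               c(6.31724137931034, 6.65775862068966), tolerance = 1e-8)
  expect_equal(glance(fit)$df.residual, 5)
})

test_that("ANCOVA recovers a constructed sex effect and handles degeneracies", {
  set.seed(21)
  n <- 400
  sex <- rep(c("F", "M"), each = n / 2)
  height <- stats::rnorm(n, ifelse(sex == "M", 1.73, 1.61), 0.04)
  value <- 5 + 2 * height + (sex == "M") * 1.0 + stats::rnorm(n, sd = 0.5)
  fit <- ancova_sex(data.frame(value, sex, height))
  expect_lt(abs(fit$sex_effect - 1.0), 0.2)
  expect_lt(fit$p, 0.05)
  # identical groups: no sex effect
  same <- data.frame(value = rep(c(5, 6, 7), 2),
                     sex = rep(c("F", "M"), each = 3),
                     height = rep(c(1.6, 1.7, 1.8), 2))
  f0 <- ancova_sex(same)
  expect_equal(f0$F, 0, tolerance = 1e-9)
  expect_gt(f0$p, 0.999)
  expect_error(ancova_sex(data.frame(value = 1:4, sex = c("F", "F", "M", "M"),
                                     height = rep(1.7, 4))), "height")
  expect_error(ancova_sex(data.frame(value = 1:4, sex = "F",
                                     height = c(1.6, 1.7, 1.8, 1.9))),
               "both sexes")
})

test_that("ANCOVA reduces to the two-sample t test when the covariate is orthogonal", {
  set.seed(5)
  n <- 60
  sex <- rep(c("F", "M"), each = n / 2)
  value <- (sex == "M") * 0.8 + stats::rnorm(n, sd = 1)
  # orthogonalize the covariate against intercept, sex and value: its fitted
  # slope is then exactly zero and the sex estimate matches the t test
  h0 <- stats::rnorm(n, 1.7, 0.05)
  height <- stats::resid(stats::lm(h0 ~ sex + value)) + 1.7
  fit <- ancova_sex(data.frame(value, sex, height))
  tt <- stats::t.test(value ~ sex, var.equal = TRUE)
  expect_lt(abs(fit$height_slope), 1e-10)
  # same statistic up to the residual-df factor (n-2 vs n-3)
  expect_equal(fit$F * (n - 2) / (n - 3), unname(tt$statistic)^2,
               tolerance = 1e-9)
  expect_equal(abs(fit$sex_effect), abs(unname(diff(tapply(value, sex, mean)))),
               tolerance = 1e-12)
})
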