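# Outlier gating, OLS/ANCOVA, bootstrap tests, paired tests, Bonferroni.

test_that("3-SD exclusion is single-pass on the full sample's mean and SD", {
  # with n = 5 the largest attainable |z| is (n-1)/sqrt(n) ~ 1.79, so even
  # an extreme value cannot exceed 3 SD and nothing is removed
  v <- c(0, 0.1, -0.1, 0.05, 50)
  ex <- exclude_outliers(v)
  expect_identical(ex$values, v)
  expect_length(ex$excluded, 0)
  expect_equal(max(abs(ex$z)), (5 - 1) / sqrt(5), tolerance = 1e-4)
  expect_lt(max(abs(ex$z)), 3)
  # the same outlier among enough inliers is removed
  set.seed(30)
  v2 <- c(rnorm(30, sd = 0.1), 50)
  ex2 <- exclude_outliers(v2)
  expect_identical(ex2$excluded, 31L)
  expect_identical(ex2$values, v2[-31])
  # degenerate SD: nothing removed
  ex3 <- exclude_outliers(rep(2, 10))
  expect_length(ex3$excluded, 0)
})

test_that("exclusion matches a brute-force reimplementation and normal tail mass", {
  set.seed(31)
  for (i in 1:30) {
    v <- rnorm(sample(12:60, 1), sd = runif(1, 0.5, 5))
    expect_identical(exclude_outliers(v)$values, naive_z_exclude(v))
  }
  set.seed(32)
  rates <- replicate(20, {
    v <- rnorm(1000)
    length(exclude_outliers(v)$excluded) / 1000
  })
  expect_lt(abs(mean(rates) - 0.0027), 0.002)
})

test_that("OLS with a constant-zero outcome gives zero coefficients and F", {
  d <- data.frame(hep_change_uv = rep(0, 24),
                  event_type = rep(c("FS", "ES"), 12),
                  semiology = rep(c("motile", "non_motile"), each = 12),
                  hr_change_bpm = rnorm(24))
  m <- fit_ols(d)
  expect_true(all(abs(stats::coef(m$fit)) < 1e-12))
  expect_true(all(m$anova[["F value"]] == 0, na.rm = TRUE))
})

test_that("duplicate-coded factors raise a rank-deficiency error", {
  set.seed(33)
  d <- data.frame(hep_change_uv = rnorm(20),
                  event_type = rep(c("FS", "ES"), 10),
                  semiology = rep(c("motile", "non_motile"), 10),
                  hr_change_bpm = rnorm(20))
  d$dup <- d$event_type
  expect_error(fit_ols(d, fixed_factors = c("event_type", "dup")),
               "rank-deficient")
  d1 <- d; d1$event_type <- "FS"
  expect_error(fit_ols(d1), "fewer than 2 levels")
})

test_that("type-II F statistics match a manual reduced-vs-full computation", {
  set.seed(34)
  d <- data.frame(event_type = sample(c("FS", "ES"), 40, TRUE),
                  semiology = sample(c("motile", "non_motile"), 40, TRUE),
                  hr_change_bpm = rnorm(40))
  d$hep_change_uv <- 2 * (d$semiology == "motile") + 0.3 * d$hr_change_bpm +
    rnorm(40)
  m <- fit_ols(d)
  full <- stats::lm(hep_change_uv ~ event_type + semiology + hr_change_bpm, d)
  red <- stats::lm(hep_change_uv ~ event_type + hr_change_bpm, d)
  f_manual <- ((sum(resid(red)^2) - sum(resid(full)^2)) / 1) /
    (sum(resid(full)^2) / full$df.residual)
  expect_equal(m$anova["semiology", "F value"], f_manual, tolerance = 1e-9)
})

test_that("one-sample bootstrap on all-zero values accepts the null", {
  r <- bootstrap_test(rep(0, 15), kind = "one_sample", seed = 3)
  expect_gte(r$p_empirical, 0.99)
  expect_false(r$significant)
})

test_that("bootstrap tests are seeded-deterministic", {
  set.seed(35)
  x <- rnorm(20, 0.5); y <- rnorm(20)
  r1 <- bootstrap_test(x, y, kind = "two_sample", seed = 9)
  r2 <- bootstrap_test(x, y, kind = "two_sample", seed = 9)
  expect_identical(r1$p_empirical, r2$p_empirical)
  expect_identical(r1$statistic, r2$statistic)
  r3 <- bootstrap_test(x, y, kind = "two_sample", seed = 10)
  expect_false(identical(r1$p_empirical, r3$p_empirical))
})

test_that("empirical p uses +1 smoothing and stays in (0, 1]", {
  set.seed(36)
  x <- rnorm(10, 5)  # overwhelming effect
  r <- bootstrap_test(x, kind = "one_sample", seed = 2)
  expect_equal(r$p_empirical, 1 / 2001, tolerance = 1e-12)
})

test_that("classical and bootstrap two-sample p agree on large Gaussian samples", {
  set.seed(37)
  x <- rnorm(150, 0.2); y <- rnorm(150)
  r <- bootstrap_test(x, y, kind = "two_sample", seed = 5)
  expect_lt(abs(r$p_classical - r$p_empirical), 0.02)
})

test_that("two-sample bootstrap has high power at a 1.5 SD separation", {
  set.seed(38)
  x <- rnorm(25); y <- rnorm(25, 1.5)
  r <- bootstrap_test(x, y, kind = "two_sample", seed = 6)
  expect_true(r$significant)
  expect_lt(r$p_empirical, 0.01)
})

test_that("the bootstrapped ANCOVA F rejects a real semiology effect only", {
  set.seed(39)
  d <- data.frame(semiology = rep(c("motile", "non_motile"), each = 15),
                  hr_change_bpm = rnorm(30))
  d$hep_change_uv <- ifelse(d$semiology == "motile", -3, 3) + rnorm(30)
  m <- fit_ols(d, fixed_factors = "semiology")
  r <- bootstrap_test(m, kind = "ols_F", term = "semiology",
                      strata = "semiology", n_resamples = 400, seed = 7)
  expect_lt(r$p_empirical, 0.02)
  d0 <- d; d0$hep_change_uv <- rnorm(30)
  m0 <- fit_ols(d0, fixed_factors = "semiology")
  r0 <- bootstrap_test(m0, kind = "ols_F", term = "semiology",
                       strata = "semiology", n_resamples = 400, seed = 8)
  expect_gt(r0$p_empirical, 0.05)
})

test_that("paired symptom test handles identity and degenerate shifts", {
  v <- rnorm(10)
  r <- paired_symptom_test(v, v)
  expect_equal(r$statistic, 0)
  expect_equal(r$p_classical, 1)
  expect_false(r$significant)
  r2 <- paired_symptom_test(v + 2, v)
  expect_true(r2$degenerate)
  expect_true(r2$significant)
  expect_error(paired_symptom_test(v, v[-1]), "mismatch")
})

test_that("paired test has the power a noncentral-t oracle predicts", {
  # n = 19, shift 2, sd 1: noncentral t with ncp = 2*sqrt(19) ~ 8.7 gives
  # power ~ 1 at alpha 0.0083; check the simulated rejection rate
  alpha <- 0.05 / 6
  crit <- qt(1 - alpha / 2, df = 18)
  power_oracle <- 1 - pt(crit, df = 18, ncp = 2 * sqrt(19)) +
    pt(-crit, df = 18, ncp = 2 * sqrt(19))
  expect_gt(power_oracle, 0.95)
  set.seed(40)
  rej <- replicate(200, {
    base <- rnorm(19)
    pre <- base + 2 + rnorm(19)  # difference sd = 1 around the +2 shift
    paired_symptom_test(pre, base)$significant
  })
  expect_gte(mean(rej), 0.95)
})

test_that("bonferroni_gate rescales alpha and recomputes significance", {
  mk <- function(p) hepline:::new_test_result("t", 1, 10, p, NA, 0, 0.05,
                                              1, 10)
  rs <- bonferroni_gate(list(mk(0.02), mk(0.001)), family_size = 4)
  expect_equal(rs[[1]]$alpha, 0.0125)
  expect_false(rs[[1]]$significant)
  expect_true(rs[[2]]$significant)
  rs6 <- bonferroni_gate(list(mk(0.01)), family_size = 6)
  expect_equal(rs6[[1]]$alpha, 0.05 / 6, tolerance = 1e-12)
  expect_equal(round(rs6[[1]]$alpha, 4), 0.0083)
  rs1 <- bonferroni_gate(list(mk(0.03)), family_size = 1)
  expect_equal(rs1[[1]]$alpha, 0.05)
  expect_true(rs1[[1]]$significant)
})
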