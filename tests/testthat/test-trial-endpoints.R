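test_that("best overall response follows the target-lesion rules", {
  # -30% boundary is inclusive: PR
  expect_equal(classify_bor(100, 70), "PR")
  expect_equal(classify_bor(100, 71), "SD")
  # nadir-based progression: nadir 80, then +21.25% and +17 mm
  expect_equal(classify_bor(100, c(80, 97)), "PD")
  # 20% up from nadir but under 5 mm absolute is not progression
  expect_equal(classify_bor(20, c(16, 19.5)), "SD")
  # complete response at sum zero wins over later assessments
  expect_equal(classify_bor(100, c(0, 40)), "CR")
  # response achieved before progression is kept as best response
  expect_equal(classify_bor(100, c(60, 130)), "PR")
  # no post-baseline assessment: not evaluable
  expect_equal(classify_bor(100, numeric(0)), "NE")
  expect_error(classify_bor(100, c(50, -1)), "negative")
  expect_error(classify_bor(0, 10), "positive")
})

test_that("response rates use the evaluable denominator", {
  bors <- c(rep("CR", 7), rep("PR", 13), rep("SD", 5), rep("PD", 9), "NE")
  rr <- response_rates(bors)
  expect_equal(rr$n_evaluable, 34)
  expect_equal(rr$orr, 100 * 20 / 34)
  expect_equal(rr$dcr, 100 * 25 / 34)
  expect_equal(response_rates(rep("PD", 5))$orr, 0)
  expect_error(response_rates(rep("NE", 3)), "no evaluable")
})

test_that("Clopper-Pearson bounds reproduce exact beta quantiles", {
  # one-sided 97.5% lower bound at 20/34
  ci <- clopper_pearson(20, 34, 0.975, "lower_one")
  expect_equal(ci$lower, qbeta(0.025, 20, 15))
  expect_equal(ci$upper, 1)
  # one-sided 97.5% lower == two-sided 95% lower
  expect_equal(ci$lower, clopper_pearson(20, 34, 0.95, "two")$lower)
  expect_equal(clopper_pearson(0, 10)$lower, 0)
  expect_equal(clopper_pearson(10, 10)$upper, 1)
  expect_error(clopper_pearson(5, 10, level = 1.2), "level")
  expect_error(clopper_pearson(11, 10), "0 <= x <= n")
  # standard-library cross-check
  ref <- binom.test(25, 34)$conf.int
  two <- clopper_pearson(25, 34, 0.95, "two")
  expect_equal(c(two$lower, two$upper), as.numeric(ref), tolerance = 1e-10)
})

test_that("24-week classification counts early losses as events", {
  pfs <- weeks_to_months(c(10, 30, 12, 24))
  ev <- c(TRUE, FALSE, FALSE, FALSE)
  res <- pfs24_classify(pfs, ev)
  # event at 10 wk: no benefit; censored at 30 wk: benefit;
  # lost to follow-up at 12 wk: event by convention; exactly 24 wk: benefit
  expect_equal(res$is_benefit, c(FALSE, TRUE, FALSE, TRUE))
  expect_equal(res$benefit, 2)
  expect_equal(res$no_benefit, 2)
})

test_that("Kaplan-Meier reduces to the empirical survival function without censoring", {
  set.seed(71)
  t <- round(rexp(40, 0.1), 2)
  km <- km_estimate(t, rep(TRUE, 40))
  ecdf_surv <- vapply(km$curve$time, function(u) mean(t > u), numeric(1))
  expect_equal(km$curve$surv, ecdf_surv, tolerance = 1e-12)
  # all censored: flat at 1, median not reached
  km2 <- km_estimate(t, rep(FALSE, 40))
  expect_true(all(km2$curve$surv == 1))
  expect_true(is.na(km2$median))
})

test_that("Kaplan-Meier matches a hand product-limit computation", {
  # classic 10-subject worked example (+ = censored):
  # 6, 6, 6, 6+, 7, 9+, 10, 10+, 11+, 13
  t <- c(6, 6, 6, 6, 7, 9, 10, 10, 11, 13)
  e <- c(TRUE, TRUE, TRUE, FALSE, TRUE, FALSE, TRUE, FALSE, FALSE, TRUE)
  km <- km_estimate(t, e)
  # hand: S(6)=7/10; S(7)=7/10*5/6; S(10)=...*3/4; S(13)=...*0
  s6 <- 7 / 10; s7 <- s6 * 5 / 6; s10 <- s7 * 3 / 4; s13 <- 0
  got <- km$curve$surv[match(c(6, 7, 10, 13), km$curve$time)]
  expect_equal(got, c(s6, s7, s10, s13), tolerance = 1e-12)
  expect_equal(km$median, 10)
})

test_that("Kaplan-Meier agrees with the survival package on censored data", {
  skip_if_not_installed("survival")
  set.seed(72)
  t <- round(rexp(60, 0.08), 2)
  cns <- round(rexp(60, 0.05), 2)
  obs <- pmin(t, cns); ev <- t <= cns
  km <- km_estimate(obs, ev, landmark = 12)
  sf <- survival::survfit(survival::Surv(obs, ev) ~ 1,
                          conf.type = "log-log")
  sm <- summary(sf, times = km$curve$time)
  expect_equal(km$curve$surv, sm$surv, tolerance = 1e-10)
  pos <- km$curve$surv > 0   # at S = 0 the reference reports NaN
  expect_equal(km$curve$se[pos], sm$std.err[pos], tolerance = 1e-8)
  idx <- !is.na(km$curve$lower)
  expect_equal(km$curve$lower[idx], sm$lower[idx], tolerance = 1e-8)
  expect_equal(km$curve$upper[idx], sm$upper[idx], tolerance = 1e-8)
  expect_equal(km$median,
               unname(summary(sf)$table["median"]))
  lm <- summary(sf, times = 12)
  expect_equal(km$landmark$surv, lm$surv, tolerance = 1e-10)
})

test_that("restricted-mean identity holds when every subject events at distinct times", {
  set.seed(73)
  t <- sort(sample(1:500, 25)) / 10
  km <- km_estimate(t, rep(TRUE, 25))
  expect_equal(km$curve$surv[nrow(km$curve)], 0)
  # integral of the step function over [0, t_max] equals the sample mean
  grid_t <- c(0, km$curve$time)
  s_prev <- c(1, head(km$curve$surv, -1))
  expect_equal(sum(diff(grid_t) * s_prev), mean(t), tolerance = 1e-12)
})

test_that("Simon two-stage operating characteristics are exact and monotone", {
  d <- two_stage_design(n1 = 23, r1 = 1, n = 40, r = 5,
                        p0 = 0.05, p1 = 0.25)
  # limits
  oc0 <- simon_oc(d, 0)
  expect_equal(oc0$prob_promising, 0)
  expect_equal(oc0$prob_early_stop, 1)
  expect_equal(oc0$expected_n, 23)
  oc1 <- simon_oc(d, 1)
  expect_equal(oc1$prob_promising, 1)
  expect_equal(oc1$expected_n, 40)
  # monotone non-decreasing promising probability on a grid
  grid_p <- seq(0, 1, by = 0.05)
  pp <- vapply(grid_p, function(p) simon_oc(d, p)$prob_promising,
               numeric(1))
  expect_true(all(diff(pp) >= -1e-12))
  # brute-force enumeration oracle over all (s1, s2) outcomes
  p <- 0.17
  brute <- sum(outer(0:23, 0:17, function(s1, s2)
    dbinom(s1, 23, p) * dbinom(s2, 17, p) *
      (s1 >= 2 & s1 + s2 >= 6)))
  expect_equal(simon_oc(d, p)$prob_promising, brute, tolerance = 1e-12)
  expect_error(two_stage_design(23, 25, 40, 5, 0.05, 0.25), "invalid")
  expect_error(two_stage_design(23, 1, 40, 5, 0.25, 0.05), "invalid")
})

test_that("a simulated trial declares promising at the enumerated frequency", {
  d <- two_stage_design(n1 = 23, r1 = 1, n = 40, r = 5,
                        p0 = 0.05, p1 = 0.25)
  p_true <- 0.15
  expected <- simon_oc(d, p_true)$prob_promising
  set.seed(74)
  n_rep <- 4000
  declared <- replicate(n_rep, {
    s1 <- rbinom(1, 23, p_true)
    s1 >= 2 && s1 + rbinom(1, 17, p_true) >= 6
  })
  mc_se <- sqrt(expected * (1 - expected) / n_rep)
  expect_lt(abs(mean(declared) - expected), 4 * mc_se)
})
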