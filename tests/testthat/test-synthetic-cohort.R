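test_that("generated cells always satisfy the marker logic", {
  p <- small_sim_params()
  for (arch in c("benefit", "no_benefit")) {
    ct <- simulate_tme(p, arch, seed = 101)
    expect_false(any(ct$TOX & !ct$PD1))     # TOX only on PD-1+ cells
    expect_false(any(ct$PD1 & !ct$CD8))     # PD-1 only on CD8+ cells
    expect_false(any(ct$CD8 & ct$FOXP3))    # lineages mutually exclusive
    expect_false(any(ct$PAX8 & ct$compartment == "stroma"))
    expect_false(any(ct$PDL1 & (ct$CD8 | ct$FOXP3)))
  }
})

test_that("the generator is deterministic given a seed", {
  p <- small_sim_params()
  a <- simulate_tme(p, "benefit", seed = 7)
  b <- simulate_tme(p, "benefit", seed = 7)
  expect_identical(as.data.frame(a), as.data.frame(b))
  f1 <- withr::local_tempfile(fileext = ".csv")
  f2 <- withr::local_tempfile(fileext = ".csv")
  write_cell_table(a, f1); write_cell_table(b, f2)
  expect_identical(readLines(f1), readLines(f2))  # byte-identical
  m1 <- simulate_mutations(p, c("benefit", "no_benefit"), seed = 9)
  m2 <- simulate_mutations(p, c("benefit", "no_benefit"), seed = 9)
  expect_identical(m1, m2)
})

test_that("degenerate configurations behave as documented", {
  # flat PD-L1 probability: assignment independent of distance, so the
  # share of PD-L1+ cells near dysfunctional T cells matches the share
  # of all eligible cells near them
  p <- small_sim_params(pdl1_max = 0.3, pdl1_base = 0.3)
  fr_pdl1 <- numeric(8); fr_all <- numeric(8)
  for (s in 1:8) {
    ct <- simulate_tme(p, "benefit", seed = 200 + s)
    eligible <- !ct$CD8 & !ct$FOXP3
    fr_pdl1[s] <- interaction_fraction(ct, "PDL1", "CD8_PD1", 50, "both")
    fr_all[s] <- interaction_fraction(ct, eligible, "CD8_PD1", 50, "both")
  }
  expect_equal(mean(fr_pdl1), mean(fr_all), tolerance = 0.05)

  # no CD8 cells: table has none and dysfunction fractions are missing
  p0 <- small_sim_params(lambda_cd8 = 0)
  ct0 <- simulate_tme(p0, "benefit", seed = 5)
  expect_equal(sum(ct0$CD8), 0)
  expect_warning(
    v <- population_fraction(ct0, "CD8_PD1", "CD8", "both"),
    "empty denominator")
  expect_true(is.na(v))

  expect_error(simulate_tme(small_sim_params(lambda_tumor = 0),
                            "benefit", seed = 1),
               "zero expected cell count")
})

test_that("dysfunction fractions converge to the configured probabilities", {
  p <- small_sim_params(lambda_cd8 = 2000)
  for (arch in c("benefit", "no_benefit")) {
    ct <- simulate_tme(p, arch, seed = 301)
    fr <- population_fraction(ct, "CD8_PD1", "CD8", "both") / 100
    expect_equal(fr, p$p_pd1_given_cd8[[arch]], tolerance = 0.1)
    fr2 <- sum(ct$TOX) / sum(ct$PD1)
    expect_equal(fr2, p$p_tox_given_pd1[[arch]], tolerance = 0.1)
  }
})

test_that("benefit archetype co-localizes PD-L1 with dysfunctional T cells", {
  p <- small_sim_params()
  fr_b <- numeric(20); fr_n <- numeric(20)
  for (s in 1:20) {
    fr_b[s] <- suppressWarnings(interaction_fraction(
      simulate_tme(p, "benefit", seed = 400 + s), "PDL1", "CD8_PD1",
      50, "tumor"))
    fr_n[s] <- suppressWarnings(interaction_fraction(
      simulate_tme(p, "no_benefit", seed = 400 + s), "PDL1", "CD8_PD1",
      50, "tumor"))
  }
  expect_gt(mean(fr_b), mean(fr_n))
})

test_that("outcome simulation respects hazards, censoring and the landmark", {
  p <- small_sim_params(hazard_pfs = c(benefit = 0, no_benefit = 0.2))
  oc <- simulate_outcomes(p, rep("benefit", 30), seed = 11)
  expect_true(all(oc$pfs24 == "benefit"))
  expect_true(all(!oc$pfs_event))
  expect_true(all(oc$pfs_months == p$censor_month))
  # censoring before the 24-week landmark with event-free draws
  p2 <- small_sim_params(hazard_pfs = c(benefit = 1e-9, no_benefit = 0.2),
                         censor_month = 5)
  oc2 <- simulate_outcomes(p2, rep("benefit", 20), seed = 12)
  expect_true(all(oc2$pfs24 == "not_evaluable"))
  # OS is never shorter than PFS
  p3 <- small_sim_params()
  oc3 <- simulate_outcomes(p3, rep(c("benefit", "no_benefit"), 25), seed = 13)
  expect_true(all(oc3$os_months >= oc3$pfs_months))
})

test_that("survival medians recover the closed-form exponential medians", {
  p <- small_sim_params(censor_month = 1000)
  oc_b <- simulate_outcomes(p, rep("benefit", 2000), seed = 21)
  oc_n <- simulate_outcomes(p, rep("no_benefit", 2000), seed = 22)
  km_b <- km_estimate(oc_b$pfs_months, oc_b$pfs_event)
  km_n <- km_estimate(oc_n$pfs_months, oc_n$pfs_event)
  expect_equal(km_b$median, log(2) / 0.02, tolerance = 0.1)
  expect_equal(km_n$median, log(2) / 0.20, tolerance = 0.1)
})

test_that("mutation profiles follow the archetype rates", {
  p <- small_sim_params()
  arch <- rep(c("benefit", "no_benefit"), c(19, 14))
  m <- simulate_mutations(p, arch, seed = 31)
  expect_equal(nrow(m$mutations), 33)
  # a zero-rate gene is never mutated
  expect_equal(sum(m$mutations$MEGF8[arch == "no_benefit"]), 0)
  # exposures are a simplex per patient
  ex <- as.matrix(m$exposures[-1])
  expect_true(all(abs(rowSums(ex) - 1) < 1e-3))
  # enumerated expectation of the Fisher p at rates (0.32, 0) and
  # n = (19, 14): sum over k of Bin(k; 19, 0.32) * p_fisher(k vs 0)
  ks <- 0:19
  p_fisher <- vapply(ks, function(k)
    fisher_exact(two_by_two(k, 19 - k, 0, 14)), numeric(1))
  expected_mean_p <- sum(dbinom(ks, 19, 0.32) * p_fisher)
  obs <- vapply(1:60, function(s) {
    mm <- simulate_mutations(p, arch, seed = 1000 + s)
    k <- sum(mm$mutations$MEGF8[arch == "benefit"])
    fisher_exact(two_by_two(k, 19 - k, 0, 14))
  }, numeric(1))
  se <- sd(obs) / sqrt(length(obs))
  expect_lt(abs(mean(obs) - expected_mean_p), 4 * se + 0.02)
})

test_that("full cohorts are reproducible and internally consistent", {
  p <- small_sim_params(n_patients = 8)
  co <- simulate_cohort(p, seed = 5)
  co2 <- simulate_cohort(p, seed = 5)
  expect_identical(co$outcomes, co2$outcomes)
  expect_identical(as.data.frame(co$cells[[3]]),
                   as.data.frame(co2$cells[[3]]))
  expect_equal(nrow(validate_cohort(co$cells, co$manifest, co$outcomes)), 0)
})
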