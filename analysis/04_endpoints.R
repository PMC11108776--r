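#!/usr/bin/env Rscript
# Stage 4: trial endpoints and design operating characteristics.
#
# Derives ORR/DCR from best overall response, the 24-week
# progression-free rate, exact Clopper-Pearson intervals (one-sided
# 97.5% lower bounds for the co-primary endpoints, two-sided 95% for
# DCR), Kaplan-Meier PFS/OS summaries, and the exact operating
# characteristics of both Simon two-stage minimax designs.

suppressPackageStartupMessages(library(dmmrtme))

oc <- read_outcomes("scratch/cohort/outcomes.csv")

rr <- response_rates(oc$bor)
n_resp <- sum(rr$counts[c("CR", "PR")])
n_dc <- sum(rr$counts[c("CR", "PR", "SD")])
orr_lb <- 100 * clopper_pearson(n_resp, rr$n_evaluable, 0.975,
                                "lower_one")$lower
dcr_ci <- clopper_pearson(n_dc, rr$n_evaluable, 0.95, "two")

p24 <- pfs24_classify(oc$pfs_months, oc$pfs_event)
n24 <- p24$benefit + p24$no_benefit
p24_lb <- 100 * clopper_pearson(p24$benefit, n24, 0.975, "lower_one")$lower

km_pfs <- km_estimate(oc$pfs_months, oc$pfs_event)
km_os <- km_estimate(oc$os_months, oc$os_event,
                     landmark = weeks_to_months(52))

cat(sprintf("ORR %.1f%% (97.5%% one-sided lower bound %.1f%%)\n",
            rr$orr, orr_lb))
cat(sprintf("DCR %.1f%% (95%% CI %.1f-%.1f%%)\n",
            rr$dcr, 100 * dcr_ci$lower, 100 * dcr_ci$upper))
cat(sprintf("PFS24 %.1f%% (97.5%% one-sided lower bound %.1f%%)\n",
            100 * p24$benefit / n24, p24_lb))
cat("Median PFS:",
    if (is.na(km_pfs$median)) "not reached"
    else sprintf("%.1f months", km_pfs$median), "\n")
cat("1-year OS:", sprintf("%.0f%%", 100 * km_os$landmark$surv), "\n")

designs <- list(
  orr = two_stage_design(23, 1, 40, 5, p0 = 0.05, p1 = 0.25),
  pfs24 = two_stage_design(17, 4, 40, 15, p0 = 0.25, p1 = 0.50))
des <- lapply(designs, function(d) {
  a <- simon_oc(d, d$p0); b <- simon_oc(d, d$p1)
  cat(sprintf("Design (n1=%d,>%d / n=%d,>%d): attained alpha %.4f, beta %.4f, E[N|p0] %.1f\n",
              d$n1, d$r1, d$n, d$r, a$prob_promising,
              1 - b$prob_promising, a$expected_n))
  list(alpha = a$prob_promising, beta = 1 - b$prob_promising,
       expected_n_null = a$expected_n,
       prob_early_stop_null = a$prob_early_stop)
})

jsonlite::write_json(
  list(n_treated = nrow(oc), n_evaluable = rr$n_evaluable,
       orr = rr$orr, orr_lb_97.5 = orr_lb,
       dcr = rr$dcr, dcr_ci_95 = list(lower = 100 * dcr_ci$lower,
                                      upper = 100 * dcr_ci$upper),
       pfs24_rate = 100 * p24$benefit / n24, pfs24_lb_97.5 = p24_lb,
       median_pfs = km_pfs$median,
       os_1yr = 100 * km_os$landmark$surv,
       designs = des),
  "results/endpoints.json", auto_unbox = TRUE, digits = NA, pretty = TRUE)
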