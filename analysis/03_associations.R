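#!/usr/bin/env Rscript
# Stage 3: benefit-group association analyses of the TME parameters.
#
# Mann-Whitney comparisons of each parameter between benefit groups,
# parameter correlation with hierarchical clustering, bottom-tertile
# dichotomization of the two model parameters with 2x2 tests and
# predictive values, and the two-covariate logistic model with ROC AUC.
# Groups are the generator's benefit/no-benefit archetypes (the
# synthetic analogue of dichotomizing by observed PFS24).

suppressPackageStartupMessages(library(dmmrtme))

bm <- read.csv("results/biomarker_matrix.csv")
arch <- read.csv("scratch/cohort/archetypes.csv")
benefit <- arch$archetype[match(bm$patient_id, arch$patient_id)] == "benefit"

pars <- setdiff(names(bm), "patient_id")
assoc <- do.call(rbind, lapply(pars, function(p) {
  v <- bm[[p]]
  ok <- !is.na(v)
  data.frame(parameter = p, n = sum(ok),
             median_benefit = median(v[ok & benefit]),
             median_no_benefit = median(v[ok & !benefit]),
             mann_whitney_p = mann_whitney(v[ok & benefit],
                                           v[ok & !benefit])$p.value)
}))
write.csv(assoc, "results/associations.csv", row.names = FALSE)
cat("Parameters with Mann-Whitney p < 0.05:",
    sum(assoc$mann_whitney_p < 0.05), "of", nrow(assoc), "\n")

cc <- correlation_cluster(bm[pars])
write.csv(as.data.frame(cc$r), "results/correlations.csv")

model_pars <- c("pct_CD8_PD1_TOX_of_CD8", "frac_PDL1_within50_of_CD8PD1")
cat("Model parameter correlation:",
    round(cc$r[model_pars[1], model_pars[2]], 3), "\n")

ok <- complete.cases(bm[model_pars])
for (p in model_pars) {
  cut <- bottom_tertile_cutoff(bm[[p]][ok])
  hi <- dichotomize_high(bm[[p]][ok], cut)
  tb <- two_by_two(sum(hi & benefit[ok]), sum(hi & !benefit[ok]),
                   sum(!hi & benefit[ok]), sum(!hi & !benefit[ok]))
  d <- diagnostics(tb)
  cat(sprintf("%s: bottom-tertile cutoff %.2f, chi-square p %.4f, PPV %.0f%%, NPV %.0f%%\n",
              p, cut, chi_square(tb)$p.value, d[["ppv"]], d[["npv"]]))
}

fit <- logistic_fit(as.matrix(bm[ok, model_pars]), benefit[ok])
roc <- roc_auc(fit$fitted, benefit[ok])
cat(sprintf("Two-parameter logistic model: AUC %.3f (n = %d)\n",
            roc$auc, sum(ok)))
jsonlite::write_json(
  list(parameters = model_pars, n = sum(ok),
       coefficients = as.list(fit$coefficients),
       converged = fit$converged, separated = fit$separated,
       auc = roc$auc),
  "results/model.json", auto_unbox = TRUE, digits = NA, pretty = TRUE)
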