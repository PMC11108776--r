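#!/usr/bin/env Rscript
# Stage 5: genomic group comparisons.
#
# TMB between benefit groups (Mann-Whitney), MSI classification at the
# MSIsensor 3.5 threshold, dominant/secondary mutational-signature
# labels, and the per-gene pathogenic-mutation scan with two-sided
# Fisher exact tests (no multiplicity adjustment).

suppressPackageStartupMessages(library(dmmrtme))

mut <- read_mutations("scratch/cohort/mutations.csv")
expos <- read_exposures("scratch/cohort/exposures.csv")
arch <- read.csv("scratch/cohort/archetypes.csv")
benefit <- arch$archetype[match(mut$patient_id, arch$patient_id)] == "benefit"

tmb_vals <- tmb(mut$n_nonsyn, mut$capture_mb)
cmp <- group_compare_tmb(tmb_vals, benefit)
cat(sprintf("TMB medians %.1f (benefit) vs %.1f (no benefit), p = %.3f\n",
            cmp$median_benefit, cmp$median_no_benefit, cmp$p.value))

msi <- msi_classify(mut$msisensor)
cat(sprintf("MSI-H: %.0f%% of %d patients\n",
            100 * mean(msi == "MSI-H"), nrow(mut)))

sig <- lapply(seq_len(nrow(expos)), function(i)
  signature_labels(unlist(expos[i, -1])))
dom_dmmr <- mean(vapply(sig, function(s) s$dominant_class == "dMMR",
                        logical(1)))
cat(sprintf("Dominant dMMR signature (6/15/20): %.0f%%\n", 100 * dom_dmmr))

gene_cols <- setdiff(names(mut),
                     c("patient_id", "n_nonsyn", "capture_mb", "msisensor"))
scan <- gene_benefit_scan(mut[gene_cols], benefit)
scan <- scan[order(scan$fisher_p), ]
write.csv(scan, "results/gene_associations.csv", row.names = FALSE)
cat("Genes with Fisher p < 0.05:\n")
hits <- scan[scan$fisher_p < 0.05, ]
if (nrow(hits) == 0) cat("  (none)\n") else
  for (i in seq_len(nrow(hits)))
    cat(sprintf("  %-8s %.0f%% vs %.0f%%, p = %.3f\n", hits$gene[i],
                hits$freq_benefit[i], hits$freq_no_benefit[i],
                hits$fisher_p[i]))

jsonlite::write_json(
  list(tmb = cmp, msi_h_pct = 100 * mean(msi == "MSI-H"),
       dominant_dmmr_pct = 100 * dom_dmmr),
  "results/genomics.json", auto_unbox = TRUE, digits = NA, pretty = TRUE)
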