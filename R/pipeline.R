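# End-to-end orchestration: simulate (or read) a cohort, build the
# biomarker matrix, run the association analyses, derive trial
# endpoints and genomic comparisons, and write a report bundle.

#' Default pipeline configuration
#'
#' All analysis thresholds surfaced in one place: interaction radius
#' (50 um), analysis compartment (tumor), MSI-H threshold (3.5),
#' 2x2 test for biomarker dichotomizations (chi-square without
#' continuity correction; Fisher available), tertile dichotomization
#' rule, the two model parameters, the trial designs, and the master
#' seed.
#'
#' @return Named list of configuration values.
#' @export
default_config <- function() {
  list(seed = 1L,
       radius = 50,
       compartment = "tumor",
       msi_threshold = 3.5,
       test = "chisq",                  # or "fisher"
       cutoff = "tertile",
       simulate = TRUE,
       model_parameters = c("pct_CD8_PD1_TOX_of_CD8",
                            "frac_PDL1_within{radius}_of_CD8PD1"),
       designs = list(
         orr = list(n1 = 23, r1 = 1, n = 40, r = 5, p0 = 0.05, p1 = 0.25),
         pfs24 = list(n1 = 17, r1 = 4, n = 40, r = 15, p0 = 0.25, p1 = 0.50)),
       inputs = NULL)                   # named paths when simulate = FALSE
}

#' Read a pipeline configuration file
#'
#' YAML file overriding any subset of [default_config()].
#'
#' @param path YAML path.
#' @return Configuration list.
#' @export
read_config <- function(path) {
  cfg <- default_config()
  user <- yaml::read_yaml(path)
  cfg[names(user)] <- user
  cfg
}

.resolve_params <- function(cfg) {
  vapply(cfg$model_parameters,
         function(p) gsub("{radius}", format(cfg$radius), p, fixed = TRUE),
         character(1), USE.NAMES = FALSE)
}

#' Run the full analysis pipeline
#'
#' Simulates a cohort (or reads one from the configured input paths),
#' validates it, computes the patient-level biomarker matrix, the
#' benefit-group association statistics (per-parameter Mann-Whitney,
#' tertile dichotomization with 2x2 test and predictive values,
#' two-covariate logistic model with ROC AUC), the trial endpoint
#' summaries (ORR/DCR/PFS24 with exact intervals, Kaplan-Meier PFS/OS,
#' Simon design operating characteristics), and the genomic group
#' comparisons, writing CSV/JSON outputs and a plain-text report under
#' `out_dir`. Deterministic for a fixed seed.
#'
#' @param out_dir Output directory (created if needed).
#' @param config Configuration list (see [default_config()]).
#' @param seed Optional seed overriding `config$seed`.
#' @param params Optional [sim_params()] overriding the defaults when
#'   simulating.
#' @return Invisibly, a list with every computed object.
#' @export
run_pipeline <- function(out_dir, config = default_config(), seed = NULL,
                         params = NULL) {
  cfg <- config
  if (!is.null(seed)) cfg$seed <- as.integer(seed)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_lines <- character(0)
  say <- function(...) {
    line <- paste0(...)
    message(line)
    log_lines <<- c(log_lines, line)
  }

  if (isTRUE(cfg$simulate)) {
    if (is.null(params)) params <- sim_params()
    say("simulate: master seed ", cfg$seed)
    cohort <- simulate_cohort(params, seed = cfg$seed)
    in_dir <- file.path(out_dir, "inputs")
    dir.create(in_dir, showWarnings = FALSE)
    for (ct in cohort$cells)
      write_cell_table(ct, file.path(in_dir,
                                     paste0(specimen_id(ct), ".csv")))
    utils::write.csv(cohort$manifest, file.path(in_dir, "manifest.csv"),
                     row.names = FALSE)
    utils::write.csv(cohort$outcomes, file.path(in_dir, "outcomes.csv"),
                     row.names = FALSE)
    utils::write.csv(cohort$mutations, file.path(in_dir, "mutations.csv"),
                     row.names = FALSE)
    utils::write.csv(cohort$exposures, file.path(in_dir, "exposures.csv"),
                     row.names = FALSE)
  } else {
    inp <- cfg$inputs
    need <- c("cells", "manifest", "outcomes", "mutations", "exposures")
    miss <- setdiff(need, names(inp))
    if (length(miss))
      stop("stage input: missing input path(s): ",
           paste(miss, collapse = ", "), call. = FALSE)
    cohort <- list(
      cells = lapply(inp$cells, read_cell_table),
      manifest = read_manifest(inp$manifest),
      outcomes = read_outcomes(inp$outcomes),
      mutations = read_mutations(inp$mutations),
      exposures = read_exposures(inp$exposures))
  }

  report <- validate_cohort(cohort$cells, cohort$manifest, cohort$outcomes)
  if (has_fatal(report))
    stop("stage validate: fatal cohort findings:\n",
         paste(report$message[report$level == "fatal"], collapse = "\n"),
         call. = FALSE)
  for (m in report$message) say("validate: ", m)

  say("biomarkers: radius ", cfg$radius, " um, compartment ",
      cfg$compartment)
  bm <- build_biomarker_matrix(cohort$cells, cohort$manifest,
                               radius = cfg$radius,
                               compartment = cfg$compartment)
  utils::write.csv(bm, file.path(out_dir, "biomarker_matrix.csv"),
                   row.names = FALSE)

  # benefit label: progression-free at 24 weeks
  oc <- cohort$outcomes
  benefit <- pfs24_classify(oc$pfs_months, oc$pfs_event)$is_benefit
  names(benefit) <- oc$patient_id
  bm_benefit <- benefit[bm$patient_id]

  pars <- setdiff(names(bm), "patient_id")
  assoc <- do.call(rbind, lapply(pars, function(p) {
    v <- bm[[p]]
    ok <- !is.na(v) & !is.na(bm_benefit)
    n_drop <- sum(!ok)
    if (n_drop) say("assoc ", p, ": ", n_drop, " missing value(s) dropped")
    x <- v[ok & bm_benefit]; y <- v[ok & !bm_benefit]
    pval <- if (length(x) && length(y)) mann_whitney(x, y)$p.value
            else NA_real_
    data.frame(parameter = p, n = sum(ok),
               median_benefit = stats::median(x),
               median_no_benefit = stats::median(y),
               mann_whitney_p = pval)
  }))
  utils::write.csv(assoc, file.path(out_dir, "associations.csv"),
                   row.names = FALSE)

  model_pars <- .resolve_params(cfg)
  model <- NULL
  if (all(model_pars %in% names(bm))) {
    ok <- stats::complete.cases(bm[model_pars]) & !is.na(bm_benefit)
    if (length(unique(bm_benefit[ok])) < 2) {
      say("model: skipped (single benefit class among complete cases)")
      ok <- rep(FALSE, length(ok))
    }
  }
  if (all(model_pars %in% names(bm)) && any(ok)) {
    X <- as.matrix(bm[ok, model_pars])
    yb <- bm_benefit[ok]
    dich <- lapply(model_pars, function(p) {
      cut <- bottom_tertile_cutoff(bm[[p]][ok])
      hi <- dichotomize_high(bm[[p]][ok], cut)
      tb <- two_by_two(sum(hi & yb), sum(hi & !yb),
                       sum(!hi & yb), sum(!hi & !yb))
      test <- if (identical(cfg$test, "fisher"))
        list(p.value = fisher_exact(tb), statistic = NA_real_)
      else chi_square(tb)
      list(parameter = p, cutoff = cut, table = unlist(tb),
           test = cfg$test, p.value = test$p.value,
           diagnostics = diagnostics(tb))
    })
    fit <- logistic_fit(X, yb)
    roc <- roc_auc(fit$fitted, yb)
    model <- list(parameters = model_pars, n = sum(ok),
                  coefficients = fit$coefficients,
                  converged = fit$converged, separated = fit$separated,
                  auc = roc$auc, dichotomizations = dich)
    say("model: AUC ", round(roc$auc, 3), " on n=", sum(ok))
    jsonlite::write_json(model, file.path(out_dir, "model.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }

  corr <- correlation_cluster(bm[setdiff(names(bm), "patient_id")])
  utils::write.csv(as.data.frame(corr$r),
                   file.path(out_dir, "correlations.csv"))

  rr <- response_rates(oc$bor)
  n_eval <- rr$n_evaluable
  n_resp <- sum(rr$counts[c("CR", "PR")])
  n_dc <- sum(rr$counts[c("CR", "PR", "SD")])
  p24 <- pfs24_classify(oc$pfs_months, oc$pfs_event)
  km_pfs <- km_estimate(oc$pfs_months, oc$pfs_event)
  km_os <- km_estimate(oc$os_months, oc$os_event,
                       landmark = weeks_to_months(52))
  des <- lapply(cfg$designs, function(d)
    do.call(two_stage_design, d))
  des_oc <- lapply(des, function(d) {
    list(alpha = simon_oc(d, d$p0)$prob_promising,
         beta = 1 - simon_oc(d, d$p1)$prob_promising,
         expected_n_null = simon_oc(d, d$p0)$expected_n,
         early_stop_null = simon_oc(d, d$p0)$prob_early_stop)
  })
  endpoints <- list(
    n_treated = nrow(oc), n_evaluable = n_eval,
    orr = rr$orr,
    orr_ci_lower_97.5_one_sided =
      100 * clopper_pearson(n_resp, n_eval, 0.975, "lower_one")$lower,
    dcr = rr$dcr,
    dcr_ci_95 = vapply(clopper_pearson(n_dc, n_eval, 0.95, "two"),
                       function(v) 100 * v, numeric(1)),
    pfs24_rate = 100 * p24$benefit / (p24$benefit + p24$no_benefit),
    pfs24_ci_lower_97.5_one_sided =
      100 * clopper_pearson(p24$benefit, p24$benefit + p24$no_benefit,
                            0.975, "lower_one")$lower,
    median_pfs_months = km_pfs$median,
    median_os_months = km_os$median,
    os_1yr = km_os$landmark,
    designs = des_oc,
    bor_counts = as.list(rr$counts))
  jsonlite::write_json(endpoints, file.path(out_dir, "endpoints.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  mut <- cohort$mutations
  mut_benefit <- benefit[mut$patient_id]
  gene_cols <- setdiff(names(mut),
                       c("patient_id", "n_nonsyn", "capture_mb", "msisensor"))
  scan <- gene_benefit_scan(mut[gene_cols], mut_benefit)
  utils::write.csv(scan, file.path(out_dir, "gene_associations.csv"),
                   row.names = FALSE)
  tmb_vals <- tmb(mut$n_nonsyn, mut$capture_mb)
  tmb_cmp <- group_compare_tmb(tmb_vals, mut_benefit)
  msi <- msi_classify(mut$msisensor, cfg$msi_threshold)
  ex <- cohort$exposures
  sig <- lapply(seq_len(nrow(ex)), function(i) {
    v <- unlist(ex[i, setdiff(names(ex), "patient_id")])
    signature_labels(v)
  })
  genomics <- list(
    tmb = tmb_cmp,
    msi_h_fraction = 100 * mean(msi == "MSI-H"),
    dominant_dmmr_fraction =
      100 * mean(vapply(sig, function(s) s$dominant_class == "dMMR",
                        logical(1))))
  jsonlite::write_json(genomics, file.path(out_dir, "genomics.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  fmt <- function(x, d = 1) formatC(x, format = "f", digits = d)
  txt <- c(
    "Cohort analysis report",
    "======================",
    sprintf("Patients treated: %d; evaluable: %d", nrow(oc), n_eval),
    sprintf("ORR %s%% (97.5%% one-sided lower bound %s%%)",
            fmt(endpoints$orr), fmt(endpoints$orr_ci_lower_97.5_one_sided)),
    sprintf("DCR %s%% (95%% CI %s%% - %s%%)", fmt(endpoints$dcr),
            fmt(endpoints$dcr_ci_95[["lower"]]),
            fmt(endpoints$dcr_ci_95[["upper"]])),
    sprintf("PFS24 %s%% (97.5%% one-sided lower bound %s%%)",
            fmt(endpoints$pfs24_rate),
            fmt(endpoints$pfs24_ci_lower_97.5_one_sided)),
    sprintf("Median PFS: %s months; median OS: %s",
            ifelse(is.na(km_pfs$median), "not reached",
                   fmt(km_pfs$median)),
            ifelse(is.na(km_os$median), "not reached", fmt(km_os$median))),
    sprintf("ORR design attained alpha %.4f, beta %.4f",
            des_oc$orr$alpha, des_oc$orr$beta),
    if (!is.null(model))
      sprintf("Two-parameter logistic model AUC %.3f (n=%d)",
              model$auc, model$n),
    sprintf("TMB medians %s vs %s (p=%.3f); MSI-H %s%%",
            fmt(tmb_cmp$median_benefit), fmt(tmb_cmp$median_no_benefit),
            tmb_cmp$p.value, fmt(genomics$msi_h_fraction)),
    "", "Log:", log_lines)
  writeLines(txt, file.path(out_dir, "report.txt"))

  invisible(list(cohort = cohort, biomarkers = bm, associations = assoc,
                 model = model, correlations = corr, endpoints = endpoints,
                 genomics = genomics, validation = report))
}
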