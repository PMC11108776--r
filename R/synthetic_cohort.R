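# Synthetic cohort generator. Emulates the structure the analysis
# assumes -- two patient archetypes (clinical benefit / no benefit)
# differing in T-cell dysfunction fractions, spatial co-localization of
# PD-L1+ cells with dysfunctional T cells, outcome distributions and
# per-gene mutation frequencies -- so every downstream stage has test
# inputs with known ground truth. Tumor nests are discs; cells follow a
# homogeneous Poisson process per compartment; PD-L1 labeling decays
# with distance to the nearest CD8+PD-1+ cell under the benefit
# archetype. A full attraction/Gibbs process is deliberately not used:
# distance-decay labeling already creates the co-localization signal
# the pipeline must detect.

# reproducible per-patient child seeds (stay below 2^31)
.child_seed <- function(master, i) (master %% 100003L) * 10007L + i * 97L

#' Simulation parameters for the synthetic cohort
#'
#' Defaults describe a 25-patient imaging cohort with a 13/25 benefit
#' rate on a 1 x 1 mm slide region. Probabilities named per archetype
#' are `c(benefit = ..., no_benefit = ...)`. Densities are cells per
#' square millimetre; times are months; distances micrometres.
#'
#' @param n_patients Number of patients.
#' @param benefit_prob Probability a patient is the benefit archetype.
#' @param region `c(width, height)` of the slide region in micrometres.
#' @param n_nests Number of circular tumor nests.
#' @param nest_radius Nest radius in micrometres.
#' @param lambda_tumor,lambda_cd8,lambda_treg,lambda_other Cell
#'   densities per mm^2 (tumor cells are confined to nests; immune and
#'   other cells cover the whole region).
#' @param p_pd1_given_cd8 Per-archetype probability a CD8+ cell is PD-1+.
#' @param p_tox_given_pd1 Per-archetype probability a CD8+PD-1+ cell is
#'   TOX+.
#' @param pdl1_max,pdl1_base,pdl1_decay_tau PD-L1 assignment: under the
#'   benefit archetype a tumor/other cell at distance `d` from the
#'   nearest CD8+PD-1+ cell is PD-L1+ with probability
#'   `pdl1_base + (pdl1_max - pdl1_base) * exp(-d / pdl1_decay_tau)`;
#'   under no benefit the probability is the constant `pdl1_base`.
#' @param hazard_pfs,hazard_os Per-archetype exponential hazards per
#'   month (OS hazard applies to the post-progression residual, so OS
#'   >= PFS by construction).
#' @param censor_month Administrative censoring time in months.
#' @param bor_probs Per-archetype probability vectors over CR/PR/SD/PD
#'   (each summing to 1).
#' @param gene_rates Per-archetype named vectors of per-gene pathogenic
#'   mutation probabilities (same gene set in both archetypes).
#' @param tmb_log_mean,tmb_log_sd Per-archetype lognormal parameters of
#'   TMB (mutations/Mb).
#' @param capture_mb Capture panel size in Mb.
#' @param msi_h_frac Fraction of patients with MSIsensor score >= 3.5.
#' @param signature_ids Signature ids simulated.
#' @param sig_alpha_msih,sig_alpha_mss Dirichlet concentration vectors
#'   for exposure draws (MSI-H draws put dominant mass on the
#'   dMMR-associated signatures 6/15/20).
#' @return A `sim_params` list.
#' @export
sim_params <- function(
    n_patients = 25,
    benefit_prob = 13 / 25,
    region = c(width = 1000, height = 1000),
    n_nests = 5,
    nest_radius = 150,
    lambda_tumor = 2500, lambda_cd8 = 300,
    lambda_treg = 100, lambda_other = 800,
    p_pd1_given_cd8 = c(benefit = 0.65, no_benefit = 0.30),
    p_tox_given_pd1 = c(benefit = 0.70, no_benefit = 0.35),
    pdl1_max = 0.6, pdl1_base = 0.15, pdl1_decay_tau = 30,
    hazard_pfs = c(benefit = 0.02, no_benefit = 0.20),
    hazard_os = c(benefit = 0.01, no_benefit = 0.08),
    censor_month = 42,
    bor_probs = list(
      benefit = c(CR = 0.35, PR = 0.50, SD = 0.10, PD = 0.05),
      no_benefit = c(CR = 0.02, PR = 0.13, SD = 0.25, PD = 0.60)),
    gene_rates = list(
      benefit = c(MEGF8 = 0.32, SETD1B = 11 / 19, PTEN = 0.76,
                  ARID1A = 0.82, PIK3CA = 0.48, JAK1 = 0.24,
                  CTNNB1 = 0.15, PTCH1 = 0.18),
      no_benefit = c(MEGF8 = 0.0, SETD1B = 2 / 14, PTEN = 0.76,
                     ARID1A = 0.82, PIK3CA = 0.48, JAK1 = 0.24,
                     CTNNB1 = 0.15, PTCH1 = 0.18)),
    tmb_log_mean = c(benefit = log(18.1), no_benefit = log(14.4)),
    tmb_log_sd = c(benefit = 0.6, no_benefit = 0.6),
    capture_mb = 30,
    msi_h_frac = 0.79,
    signature_ids = c(1, 5, 6, 10, 15, 20),
    sig_alpha_msih = c(1.0, 0.5, 6.0, 0.1, 2.0, 1.5),
    sig_alpha_mss = c(6.0, 2.0, 1.5, 0.3, 0.5, 0.5)) {
  p <- as.list(environment())
  probs <- c(p$benefit_prob, p$p_pd1_given_cd8, p$p_tox_given_pd1,
             p$pdl1_max, p$pdl1_base, p$msi_h_frac,
             unlist(p$bor_probs), unlist(p$gene_rates))
  if (any(probs < 0 | probs > 1))
    stop("sim_params: probabilities must lie in [0, 1]", call. = FALSE)
  for (arch in names(p$bor_probs))
    if (abs(sum(p$bor_probs[[arch]]) - 1) > 1e-9)
      stop("sim_params: bor_probs[", arch, "] must sum to 1", call. = FALSE)
  if (!identical(sort(names(p$gene_rates$benefit)),
                 sort(names(p$gene_rates$no_benefit))))
    stop("sim_params: gene sets differ between archetypes", call. = FALSE)
  if (any(c(p$hazard_pfs, p$hazard_os) < 0) || p$censor_month <= 0 ||
      p$pdl1_decay_tau <= 0)
    stop("sim_params: rates must be non-negative and scales positive",
         call. = FALSE)
  class(p) <- "sim_params"
  p
}

#' Simulate one specimen's cell table
#'
#' Tumor nests are discs placed uniformly inside the region; tumor
#' (Pax8+) cells follow a homogeneous Poisson process inside the nest
#' union, while CD8+, FoxP3+ and unlabeled "other" cells cover the whole
#' region (compartment assigned by nest membership). Marker logic holds
#' by construction: Pax8+ iff tumor cell, CD8 and FoxP3 mutually
#' exclusive, PD-1 only on CD8+ cells, TOX only on CD8+PD-1+ cells.
#' PD-L1 is assigned to tumor and other cells with a probability that
#' decays with distance to the nearest CD8+PD-1+ cell under the benefit
#' archetype and is flat under no benefit. Deterministic given the seed.
#'
#' @param params A [sim_params] object.
#' @param archetype `"benefit"` or `"no_benefit"`.
#' @param seed Integer seed.
#' @param specimen_id Specimen id string.
#' @return A [cell_table].
#' @export
simulate_tme <- function(params, archetype = c("benefit", "no_benefit"),
                         seed, specimen_id = "S1") {
  stopifnot(inherits(params, "sim_params"))
  archetype <- match.arg(archetype)
  w <- params$region[["width"]]; h <- params$region[["height"]]
  area_mm2 <- w * h / 1e6
  if (params$n_nests < 1 || params$nest_radius <= 0 ||
      params$lambda_tumor * area_mm2 <= 0)
    stop("zero expected cell count in tumor compartment", call. = FALSE)
  if ((params$lambda_cd8 + params$lambda_treg + params$lambda_other) *
        area_mm2 <= 0)
    stop("zero expected cell count in stroma compartment", call. = FALSE)
  set.seed(seed)
  r <- params$nest_radius
  cx <- stats::runif(params$n_nests, min(r, w / 2), max(w - r, w / 2))
  cy <- stats::runif(params$n_nests, min(r, h / 2), max(h - r, h / 2))
  in_nest <- function(x, y) {
    inside <- rep(FALSE, length(x))
    for (k in seq_len(params$n_nests))
      inside <- inside | ((x - cx[k])^2 + (y - cy[k])^2 <= r^2)
    inside
  }
  draw <- function(lambda) {
    n <- stats::rpois(1, lambda * area_mm2)
    list(x = stats::runif(n, 0, w), y = stats::runif(n, 0, h))
  }
  # tumor cells: Poisson over the region thinned to the nest union
  tu <- draw(params$lambda_tumor)
  keep <- in_nest(tu$x, tu$y)
  tu$x <- tu$x[keep]; tu$y <- tu$y[keep]
  cd8 <- draw(params$lambda_cd8)
  trg <- draw(params$lambda_treg)
  oth <- draw(params$lambda_other)
  lineage <- c(rep("tumor", length(tu$x)), rep("cd8", length(cd8$x)),
               rep("treg", length(trg$x)), rep("other", length(oth$x)))
  x <- round(c(tu$x, cd8$x, trg$x, oth$x), 2)
  y <- round(c(tu$y, cd8$y, trg$y, oth$y), 2)
  n <- length(x)
  compartment <- ifelse(in_nest(x, y), "tumor", "stroma")
  cell_id <- sprintf("%s_c%05d", specimen_id, seq_len(n))
  CD8 <- lineage == "cd8"
  FOXP3 <- lineage == "treg"
  PAX8 <- lineage == "tumor"
  PD1 <- CD8 & stats::runif(n) < params$p_pd1_given_cd8[[archetype]]
  TOX <- PD1 & stats::runif(n) < params$p_tox_given_pd1[[archetype]]
  eligible <- lineage %in% c("tumor", "other")
  p_pdl1 <- rep(0, n)
  if (archetype == "benefit" && any(PD1)) {
    d <- .nn_grid(x[eligible], y[eligible], cell_id[eligible],
                  x[PD1], y[PD1], cell_id[PD1])
    p_pdl1[eligible] <- params$pdl1_base +
      (params$pdl1_max - params$pdl1_base) * exp(-d / params$pdl1_decay_tau)
  } else {
    p_pdl1[eligible] <- params$pdl1_base
  }
  PDL1 <- stats::runif(n) < p_pdl1
  cell_table(specimen_id, cell_id, x, y, compartment,
             data.frame(CD8 = CD8, PD1 = PD1, TOX = TOX, FOXP3 = FOXP3,
                        PDL1 = PDL1, PAX8 = PAX8))
}

#' Simulate patient outcomes
#'
#' PFS is exponential with the archetype hazard; OS adds an independent
#' exponential residual so OS >= PFS by construction; both are
#' administratively censored at `censor_month`. The 24-week status is
#' benefit when the patient is progression-free at 24 weeks, no benefit
#' when an event occurred earlier, and not evaluable when censored
#' event-free before 24 weeks. Best overall response is drawn from the
#' archetype's category probabilities.
#'
#' @param params A [sim_params] object.
#' @param archetypes Character vector, one archetype per patient.
#' @param seed Integer master seed (per-patient child seeds derived by
#'   fixed arithmetic, so cohorts are reproducible under subsetting).
#' @return Data frame with `patient_id`, `bor`, `pfs_months`,
#'   `pfs_event`, `os_months`, `os_event`, `pfs24`.
#' @export
simulate_outcomes <- function(params, archetypes, seed) {
  stopifnot(inherits(params, "sim_params"),
            all(archetypes %in% c("benefit", "no_benefit")))
  t24 <- .PFS24_MONTHS
  rows <- lapply(seq_along(archetypes), function(i) {
    arch <- archetypes[i]
    set.seed(.child_seed(seed, i))
    h_pfs <- params$hazard_pfs[[arch]]
    pfs_raw <- if (h_pfs > 0) stats::rexp(1, h_pfs) else Inf
    h_os <- params$hazard_os[[arch]]
    os_raw <- pfs_raw + if (h_os > 0) stats::rexp(1, h_os) else Inf
    cm <- params$censor_month
    pfs_event <- pfs_raw <= cm
    pfs_months <- min(pfs_raw, cm)
    os_event <- os_raw <= cm
    os_months <- min(os_raw, cm)
    pfs24 <- if (pfs_months >= t24) "benefit"
             else if (pfs_event) "no_benefit"
             else "not_evaluable"
    bor <- sample(names(params$bor_probs[[arch]]), 1,
                  prob = params$bor_probs[[arch]])
    data.frame(patient_id = sprintf("P%03d", i), bor = bor,
               pfs_months = pfs_months, pfs_event = pfs_event,
               os_months = os_months, os_event = os_event, pfs24 = pfs24)
  })
  do.call(rbind, rows)
}

#' Simulate mutation profiles
#'
#' Per-gene independent Bernoulli flags by archetype rate; TMB
#' lognormal (converted to a nonsynonymous count through the capture
#' size); MSIsensor score drawn so a configurable fraction exceeds the
#' 3.5 MSI-H threshold; signature exposures Dirichlet with dominant
#' mass on the dMMR-associated signatures for MSI-H draws.
#'
#' @inheritParams simulate_outcomes
#' @return List with `mutations` (patient_id, per-gene 0/1 flags,
#'   `n_nonsyn`, `capture_mb`, `msisensor`) and `exposures`
#'   (patient_id, one column per signature id).
#' @export
simulate_mutations <- function(params, archetypes, seed) {
  stopifnot(inherits(params, "sim_params"))
  genes <- names(params$gene_rates$benefit)
  sig_ids <- params$signature_ids
  rows <- lapply(seq_along(archetypes), function(i) {
    arch <- archetypes[i]
    set.seed(.child_seed(seed, i) + 1L)
    flags <- as.integer(stats::runif(length(genes)) <
                          params$gene_rates[[arch]][genes])
    tmb_val <- stats::rlnorm(1, params$tmb_log_mean[[arch]],
                             params$tmb_log_sd[[arch]])
    n_nonsyn <- max(0L, round(tmb_val * params$capture_mb))
    msih <- stats::runif(1) < params$msi_h_frac
    score <- if (msih) 3.5 + stats::rexp(1, 1 / 8) else stats::runif(1, 0, 3.4)
    alpha <- if (msih) params$sig_alpha_msih else params$sig_alpha_mss
    g <- stats::rgamma(length(sig_ids), shape = alpha)
    expo <- g / sum(g)
    mut <- data.frame(patient_id = sprintf("P%03d", i))
    mut[genes] <- as.list(flags)
    mut$n_nonsyn <- n_nonsyn
    mut$capture_mb <- params$capture_mb
    mut$msisensor <- round(score, 3)
    ex <- data.frame(patient_id = sprintf("P%03d", i))
    ex[as.character(sig_ids)] <- as.list(round(expo, 6))
    list(mut = mut, ex = ex)
  })
  list(mutations = do.call(rbind, lapply(rows, `[[`, "mut")),
       exposures = do.call(rbind, lapply(rows, `[[`, "ex")))
}

#' Simulate a full cohort
#'
#' Draws one archetype per patient, one specimen per patient (cell
#' table), outcomes and mutation profiles, all reproducible from one
#' master seed via fixed per-patient child seeds.
#'
#' @param params A [sim_params] object.
#' @param seed Integer master seed.
#' @return List with `cells` (list of [cell_table]), `manifest`,
#'   `outcomes`, `mutations`, `exposures`, and `archetypes` (data frame
#'   `patient_id`, `archetype`).
#' @export
simulate_cohort <- function(params = sim_params(), seed = 1L) {
  stopifnot(inherits(params, "sim_params"))
  set.seed(seed)
  arch <- ifelse(stats::runif(params$n_patients) < params$benefit_prob,
                 "benefit", "no_benefit")
  ids <- sprintf("P%03d", seq_len(params$n_patients))
  cells <- lapply(seq_len(params$n_patients), function(i)
    simulate_tme(params, arch[i], seed = .child_seed(seed, i) + 2L,
                 specimen_id = sprintf("%s_sp1", ids[i])))
  manifest <- data.frame(specimen_id = sprintf("%s_sp1", ids),
                         patient_id = ids)
  outcomes <- simulate_outcomes(params, arch, seed)
  muts <- simulate_mutations(params, arch, seed)
  list(cells = cells, manifest = manifest, outcomes = outcomes,
       mutations = muts$mutations, exposures = muts$exposures,
       archetypes = data.frame(patient_id = ids, archetype = arch))
}
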