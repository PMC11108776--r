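# Downstream genomic summaries and benefit-group comparisons from
# precomputed per-patient profiles. Signature inference and MSI scoring
# are upstream tools whose outputs this module consumes; its contract
# starts at their outputs.

#' Tumor mutational burden
#'
#' Nonsynonymous somatic mutation count divided by the capture size in
#' megabases.
#'
#' @param n_nonsyn Nonsynonymous mutation count(s), >= 0.
#' @param capture_mb Capture panel size in Mb, > 0.
#' @return Mutations per megabase.
#' @export
tmb <- function(n_nonsyn, capture_mb) {
  if (any(capture_mb <= 0)) stop("tmb: capture size must be positive",
                                 call. = FALSE)
  if (any(n_nonsyn < 0)) stop("tmb: negative mutation count", call. = FALSE)
  n_nonsyn / capture_mb
}

#' Microsatellite-instability classification
#'
#' MSI-high iff the MSIsensor score is at least the threshold (boundary
#' inclusive; default 3.5), else microsatellite stable.
#'
#' @param score MSIsensor score(s), finite.
#' @param threshold Classification threshold (default 3.5).
#' @return Character vector of `"MSI-H"` / `"MSS"`.
#' @export
msi_classify <- function(score, threshold = 3.5) {
  if (any(!is.finite(score))) stop("msi_classify: non-finite score",
                                   call. = FALSE)
  ifelse(score >= threshold, "MSI-H", "MSS")
}

#' Default mutational-signature class map
#'
#' Signatures 6, 15 and 20 are mismatch-repair-deficiency associated;
#' 1 and 5 are taken as the aging-related set; 10 is polymerase-epsilon
#' associated; anything else is `"other"`. The aging set is an
#' assumption (conventionally clock-like) and the map is configurable.
#'
#' @return Named list mapping class name to signature ids.
#' @export
default_signature_classes <- function()
  list(dMMR = c(6, 15, 20), aging = c(1, 5), POLE = 10)

#' Dominant and secondary mutational-signature labels
#'
#' The dominant signature is the one with the largest exposure and the
#' secondary the second largest; ties are broken deterministically
#' toward the smaller signature id and flagged. The dominant
#' signature's class is looked up in the class map.
#'
#' @param exposures Named numeric vector of signature exposures in
#'   \[0, 1\] (names are signature ids); at least one must be positive.
#' @param classes Class map as in [default_signature_classes()].
#' @return List with `dominant`, `secondary` (signature ids as
#'   numeric; `secondary` `NA` if only one signature), `dominant_class`,
#'   and `tie` (logical).
#' @export
signature_labels <- function(exposures, classes = default_signature_classes()) {
  ids <- suppressWarnings(as.numeric(names(exposures)))
  if (anyNA(ids)) stop("signature_labels: non-numeric signature ids",
                       call. = FALSE)
  w <- as.numeric(exposures)
  if (all(w <= 0)) stop("signature_labels: all exposures are zero",
                        call. = FALSE)
  ord <- order(-w, ids)   # largest exposure first, smaller id on ties
  dominant <- ids[ord[1]]
  tie <- sum(w == max(w)) > 1
  secondary <- if (length(ids) > 1 && w[ord[2]] > 0) ids[ord[2]] else NA_real_
  cls <- "other"
  for (nm in names(classes)) if (dominant %in% classes[[nm]]) { cls <- nm; break }
  list(dominant = dominant, secondary = secondary,
       dominant_class = cls, tie = tie)
}

#' Per-gene mutation-frequency scan against clinical benefit
#'
#' For every gene, the pathogenic-mutation frequency in the benefit and
#' no-benefit groups and a two-sided Fisher exact p-value
#' ([fisher_exact()], minimum-likelihood rule). No multiplicity
#' adjustment is applied. Patients with a missing flag for a gene are
#' excluded pairwise for that gene, with a message reporting the count.
#'
#' @param gene_flags Data frame or matrix of logical/0-1 mutation flags,
#'   one column per gene, one row per patient (`NA` allowed).
#' @param benefit Logical vector: TRUE = clinical benefit. Both groups
#'   must be non-empty.
#' @return Data frame with `gene`, `n_benefit`, `n_no_benefit`,
#'   `freq_benefit`, `freq_no_benefit` (percent) and `fisher_p`.
#' @export
gene_benefit_scan <- function(gene_flags, benefit) {
  gene_flags <- as.data.frame(gene_flags)
  benefit <- as.logical(benefit)
  stopifnot(nrow(gene_flags) == length(benefit))
  if (!any(benefit) || all(benefit))
    stop("gene_benefit_scan: both groups must be non-empty", call. = FALSE)
  rows <- lapply(names(gene_flags), function(g) {
    flag <- as.logical(gene_flags[[g]])
    ok <- !is.na(flag)
    if (any(!ok))
      message("gene ", g, ": ", sum(!ok), " patient(s) with missing flag ",
              "excluded")
    f <- flag[ok]; b <- benefit[ok]
    a_ <- sum(f & b); b_ <- sum(f & !b); c_ <- sum(!f & b); d_ <- sum(!f & !b)
    nb <- a_ + c_; nn <- b_ + d_
    data.frame(gene = g, n_benefit = nb, n_no_benefit = nn,
               freq_benefit = if (nb) 100 * a_ / nb else NA_real_,
               freq_no_benefit = if (nn) 100 * b_ / nn else NA_real_,
               fisher_p = if (nb && nn) fisher_exact(two_by_two(a_, b_, c_, d_))
                          else NA_real_)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Compare tumor mutational burden between benefit groups
#'
#' Group medians and a two-sided Mann-Whitney p-value
#' ([mann_whitney()]).
#'
#' @param tmb_values Numeric TMB values (mutations per Mb).
#' @param benefit Logical benefit labels; both groups non-empty.
#' @return List with `median_benefit`, `median_no_benefit`, `p.value`.
#' @export
group_compare_tmb <- function(tmb_values, benefit) {
  benefit <- as.logical(benefit)
  x <- tmb_values[benefit]; y <- tmb_values[!benefit]
  if (!length(x) || !length(y))
    stop("group_compare_tmb: both groups must be non-empty", call. = FALSE)
  mw <- mann_whitney(x, y)
  list(median_benefit = stats::median(x, na.rm = TRUE),
       median_no_benefit = stats::median(y, na.rm = TRUE),
       p.value = mw$p.value)
}
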