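#' Marker panel
#'
#' The six-marker multiplexed-immunofluorescence panel this pipeline
#' consumes: CD8 (cytotoxic T cells), PD1 (chronic antigen stimulation /
#' dysfunction), TOX (terminal dysfunction), FOXP3 (regulatory T cells),
#' PDL1 (PD-L1 ligand), PAX8 (Muellerian tumor-cell lineage).
#'
#' @format Character vector of length 6.
#' @export
PANEL_MARKERS <- c("CD8", "PD1", "TOX", "FOXP3", "PDL1", "PAX8")

#' Convert weeks to months
#'
#' One central conversion used for every landmark (24 weeks, 1 year):
#' `weeks * 7 / 30.4375` where 30.4375 is the mean Gregorian month length
#' in days. `weeks_to_months(24)` is 5.519507 months, the PFS24 landmark.
#'
#' @param weeks Numeric vector of week counts.
#' @return Months as a numeric vector.
#' @export
weeks_to_months <- function(weeks) weeks * 7 / 30.4375

# 24-week landmark in months, used by pfs24 classification and simulation
.PFS24_MONTHS <- 24 * 7 / 30.4375
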