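#' Define a cell phenotype by marker gates
#'
#' A phenotype is a conjunction of required-positive and
#' required-negative marker calls, e.g. dysfunctional T cells are
#' CD8+PD-1+ and terminally dysfunctional T cells CD8+PD-1+TOX+.
#' Phenotypes may nest: every CD8+PD-1+TOX+ cell is also CD8+PD-1+.
#'
#' @param name Phenotype name.
#' @param positive Markers that must be positive.
#' @param negative Markers that must be negative (default none).
#' @return A `phenotype_def`.
#' @export
phenotype_def <- function(name, positive, negative = character(0)) {
  positive <- as.character(positive); negative <- as.character(negative)
  unknown <- setdiff(c(positive, negative), PANEL_MARKERS)
  if (length(unknown))
    stop("phenotype '", name, "' references unknown marker(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  if (length(intersect(positive, negative)))
    stop("phenotype '", name, "' requires a marker both + and -",
         call. = FALSE)
  structure(list(name = name, positive = positive, negative = negative),
            class = "phenotype_def")
}

#' Panel phenotypes used throughout the analysis
#'
#' CD8 (cytotoxic T), CD8_PD1 (dysfunctional T), CD8_PD1_TOX (terminally
#' dysfunctional T), FOXP3 (Treg), PDL1 (any PD-L1+ cell), PDL1_tumor
#' (PD-L1+ Pax8+ tumor cell), PAX8 (tumor cell).
#'
#' @return Named list of [phenotype_def] objects.
#' @export
default_phenotypes <- function() {
  list(CD8         = phenotype_def("CD8", "CD8"),
       CD8_PD1     = phenotype_def("CD8_PD1", c("CD8", "PD1")),
       CD8_PD1_TOX = phenotype_def("CD8_PD1_TOX", c("CD8", "PD1", "TOX")),
       FOXP3       = phenotype_def("FOXP3", "FOXP3"),
       PDL1        = phenotype_def("PDL1", "PDL1"),
       PDL1_tumor  = phenotype_def("PDL1_tumor", c("PDL1", "PAX8")),
       PAX8        = phenotype_def("PAX8", "PAX8"))
}

# resolve a phenotype argument (def, name, or logical mask) to a mask
.pheno_mask <- function(cells, pheno) {
  if (is.logical(pheno)) {
    stopifnot(length(pheno) == nrow(cells))
    return(pheno)
  }
  if (is.character(pheno)) {
    defs <- default_phenotypes()
    if (!pheno %in% names(defs))
      stop("unknown phenotype name '", pheno, "'", call. = FALSE)
    pheno <- defs[[pheno]]
  }
  stopifnot(inherits(pheno, "phenotype_def"))
  mask <- rep(TRUE, nrow(cells))
  for (m in pheno$positive) mask <- mask & cells[[m]]
  for (m in pheno$negative) mask <- mask & !cells[[m]]
  mask
}

# restrict a cell table to an analysis compartment
.in_compartment <- function(cells, compartment = c("tumor", "stroma", "both")) {
  compartment <- match.arg(compartment)
  if (compartment == "both") rep(TRUE, nrow(cells))
  else cells$compartment == compartment
}

#' Gate cells into phenotypes
#'
#' @param cells A [cell_table].
#' @param defs List of [phenotype_def] objects (default
#'   [default_phenotypes()]).
#' @return Logical matrix, one row per cell and one column per
#'   phenotype; a cell may match several (nested) phenotypes.
#' @export
classify <- function(cells, defs = default_phenotypes()) {
  out <- vapply(defs, function(d) .pheno_mask(cells, d),
                logical(nrow(cells)))
  if (nrow(cells) == 1L) out <- matrix(out, nrow = 1L,
                                       dimnames = list(NULL, names(defs)))
  colnames(out) <- vapply(defs, function(d) d$name, character(1))
  rownames(out) <- cells$cell_id
  out
}

#' Population fraction of a phenotype
#'
#' Percentage of cells of a phenotype among a denominator population,
#' within an analysis compartment. The reporting convention is
#' percentages out of total nucleated cells unless a different
#' denominator (e.g. the CD8 compartment) is requested. An empty
#' denominator yields a missing value with a warning, not an error.
#'
#' @param cells A [cell_table].
#' @param phenotype Phenotype (def, name, or logical mask).
#' @param denominator `"total_nucleated"`, a phenotype name, a
#'   [phenotype_def], or a logical mask.
#' @param compartment `"tumor"` (default, matching the reported
#'   analyses), `"stroma"` or `"both"`.
#' @return Percent in \[0, 100\], or `NA` when the denominator is empty.
#' @export
population_fraction <- function(cells, phenotype,
                                denominator = "total_nucleated",
                                compartment = "tumor") {
  comp <- .in_compartment(cells, compartment)
  num <- .pheno_mask(cells, phenotype) & comp
  den <- if (identical(denominator, "total_nucleated")) comp
         else .pheno_mask(cells, denominator) & comp
  if (!sum(den)) {
    warning("empty denominator; fraction is missing", call. = FALSE)
    return(NA_real_)
  }
  100 * sum(num & den) / sum(den)
}

#' CD8 to FoxP3 cell-count ratio
#'
#' @inheritParams population_fraction
#' @return `|CD8+| / |FoxP3+|` in the compartment; `NA` when no FoxP3+
#'   cell is present.
#' @export
cd8_foxp3_ratio <- function(cells, compartment = "tumor") {
  comp <- .in_compartment(cells, compartment)
  n_cd8 <- sum(cells$CD8 & comp)
  n_foxp3 <- sum(cells$FOXP3 & comp)
  if (!n_foxp3) return(NA_real_)
  n_cd8 / n_foxp3
}

#' PD-L1 positivity
#'
#' Percentage of PD-L1+ cells either among Pax8+ tumor cells
#' (`scope = "tumor_cells"`) or among all cells (`scope = "combined"`,
#' i.e. tumor and immune cells together), both within the tumor
#' compartment by default.
#'
#' @inheritParams population_fraction
#' @param scope `"tumor_cells"` or `"combined"`.
#' @return Percent, or `NA` when the scope denominator is empty.
#' @export
pdl1_positivity <- function(cells, scope = c("tumor_cells", "combined"),
                            compartment = "tumor") {
  scope <- match.arg(scope)
  comp <- .in_compartment(cells, compartment)
  den <- if (scope == "tumor_cells") cells$PAX8 & comp else comp
  if (!sum(den)) return(NA_real_)
  100 * sum(cells$PDL1 & den) / sum(den)
}

#' Average per-specimen values into one per-patient value
#'
#' Patients with more than one archival specimen contribute the
#' unweighted arithmetic mean of their per-specimen measurements (not a
#' cell-weighted pool); missing specimen values are dropped.
#'
#' @param values Numeric vector of per-specimen values, `NA` allowed.
#' @return Mean of the non-missing values; `NA` if all are missing.
#' @export
patient_average <- function(values) {
  v <- values[!is.na(values)]
  if (!length(v)) return(NA_real_)
  mean(v)
}
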