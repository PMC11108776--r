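# Low-level neighbor search on planar coordinates (micrometres).
#
# Two interchangeable routes: a brute-force O(|A|*|B|) double loop and a
# uniform-grid bucket search (ring expansion for nearest neighbors, 3x3
# neighborhood for fixed-radius queries). Both are exact; the grid route
# exists for speed and the brute-force route doubles as its oracle.
# Self-pairs (same cell id in both classes) are always excluded: a cell
# is never its own neighbor.

.nn_brute <- function(ax, ay, aid, bx, by, bid) {
  n <- length(ax)
  out <- rep(NA_real_, n)
  if (!length(bx)) return(out)
  for (i in seq_len(n)) {
    d2 <- (bx - ax[i])^2 + (by - ay[i])^2
    d2[bid == aid[i]] <- Inf
    m <- min(d2)
    out[i] <- if (is.finite(m)) sqrt(m) else NA_real_
  }
  out
}

.nn_grid <- function(ax, ay, aid, bx, by, bid) {
  n <- length(ax)
  out <- rep(NA_real_, n)
  nb <- length(bx)
  if (!nb) return(out)
  minx <- min(bx); miny <- min(by)
  ext <- max(max(bx) - minx, max(by) - miny)
  if (ext <= 0) return(.nn_brute(ax, ay, aid, bx, by, bid))
  h <- ext / max(1L, floor(sqrt(nb)))
  nx <- floor((max(bx) - minx) / h) + 1L
  ny <- floor((max(by) - miny) / h) + 1L
  bix <- pmin(floor((bx - minx) / h), nx - 1L)
  biy <- pmin(floor((by - miny) / h), ny - 1L)
  buckets <- split(seq_len(nb), bix * ny + biy)
  for (i in seq_len(n)) {
    qix <- floor((ax[i] - minx) / h)
    qiy <- floor((ay[i] - miny) / h)
    rmax <- max(abs(qix), abs(qix - (nx - 1L)), abs(qiy), abs(qiy - (ny - 1L)))
    best <- Inf
    for (r in 0:rmax) {
      if (is.finite(best) && (r - 1) * h > sqrt(best)) break
      xlo <- max(0L, qix - r); xhi <- min(nx - 1L, qix + r)
      ylo <- max(0L, qiy - r); yhi <- min(ny - 1L, qiy + r)
      if (xlo > xhi || ylo > yhi) next
      ys <- ylo:yhi
      keys <- if (r == 0L) {
        if (qix < 0L || qix >= nx || qiy < 0L || qiy >= ny) character(0)
        else as.character(qix * ny + qiy)
      } else {
        xs_mid <- xlo:xhi
        xs_mid <- xs_mid[xs_mid > qix - r & xs_mid < qix + r]
        cand <- c(if (qix - r >= 0L && qix - r < nx)
                    (qix - r) * ny + ys,
                  if (qix + r >= 0L && qix + r < nx)
                    (qix + r) * ny + ys,
                  unlist(lapply(xs_mid, function(cx)
                    c(if (qiy - r >= 0L && qiy - r < ny) cx * ny + qiy - r,
                      if (qiy + r >= 0L && qiy + r < ny) cx * ny + qiy + r))))
        as.character(unique(cand))
      }
      for (k in keys) {
        idx <- buckets[[k]]
        if (is.null(idx)) next
        d2 <- (bx[idx] - ax[i])^2 + (by[idx] - ay[i])^2
        d2[bid[idx] == aid[i]] <- Inf
        m <- min(d2)
        if (m < best) best <- m
      }
    }
    out[i] <- if (is.finite(best)) sqrt(best) else NA_real_
  }
  out
}

# TRUE for each target with an anchor (other than itself) within radius
.within_radius_brute <- function(tx, ty, tid, ax, ay, aid, radius) {
  n <- length(tx)
  out <- logical(n)
  if (!length(ax)) return(out)
  r2 <- radius^2
  for (i in seq_len(n)) {
    d2 <- (ax - tx[i])^2 + (ay - ty[i])^2
    d2[aid == tid[i]] <- Inf
    out[i] <- any(d2 <= r2)
  }
  out
}

.within_radius_grid <- function(tx, ty, tid, ax, ay, aid, radius) {
  n <- length(tx)
  out <- logical(n)
  na <- length(ax)
  if (!na) return(out)
  h <- radius
  minx <- min(ax); miny <- min(ay)
  nx <- floor((max(ax) - minx) / h) + 1L
  ny <- floor((max(ay) - miny) / h) + 1L
  aix <- pmin(floor((ax - minx) / h), nx - 1L)
  aiy <- pmin(floor((ay - miny) / h), ny - 1L)
  buckets <- split(seq_len(na), aix * ny + aiy)
  r2 <- radius^2
  for (i in seq_len(n)) {
    qix <- floor((tx[i] - minx) / h)
    qiy <- floor((ty[i] - miny) / h)
    xlo <- max(0L, qix - 1L); xhi <- min(nx - 1L, qix + 1L)
    ylo <- max(0L, qiy - 1L); yhi <- min(ny - 1L, qiy + 1L)
    hit <- FALSE
    if (xlo <= xhi && ylo <= yhi) {
      for (cx in xlo:xhi) {
        if (hit) break
        for (cy in ylo:yhi) {
          idx <- buckets[[as.character(cx * ny + cy)]]
          if (is.null(idx)) next
          d2 <- (ax[idx] - tx[i])^2 + (ay[idx] - ty[i])^2
          d2[aid[idx] == tid[i]] <- Inf
          if (any(d2 <= r2)) { hit <- TRUE; break }
        }
      }
    }
    out[i] <- hit
  }
  out
}

.spatial_subset <- function(cells, pheno, comp) {
  mask <- .pheno_mask(cells, pheno) & comp
  list(x = cells$x[mask], y = cells$y[mask], id = cells$cell_id[mask])
}

#' Nearest-neighbor distances between two phenotype classes
#'
#' For each cell of the `from` phenotype, the Euclidean distance in
#' micrometres to the nearest cell of the `to` phenotype on the same
#' slide. A cell belonging to both classes is matched to the nearest
#' *other* member of the target class. When no target cell exists, every
#' distance is missing. No edge correction is applied: the estimator is
#' the plain within-slide distance, border effects included.
#'
#' @param cells A [cell_table].
#' @param from,to Phenotypes (def, name, or logical mask).
#' @param compartment Compartment restriction (default `"both"`).
#' @param method `"grid"` (accelerated, default) or `"brute"`
#'   (reference double loop); the two are exactly equal.
#' @return Numeric vector, one distance per `from` cell (in the order
#'   they appear in the table), `NA` when the target class is empty.
#' @export
nn_distances <- function(cells, from, to, compartment = "both",
                         method = c("grid", "brute")) {
  method <- match.arg(method)
  comp <- .in_compartment(cells, compartment)
  a <- .spatial_subset(cells, from, comp)
  b <- .spatial_subset(cells, to, comp)
  f <- if (method == "grid") .nn_grid else .nn_brute
  f(a$x, a$y, a$id, b$x, b$y, b$id)
}

#' Median nearest-neighbor distance
#'
#' Median of [nn_distances()] over the `from` cells; with an even count
#' the mean of the two central order statistics. Missing when no
#' distance is defined.
#'
#' @inheritParams nn_distances
#' @return Median distance in micrometres, or `NA`.
#' @export
median_nn_distance <- function(cells, from, to, compartment = "both",
                               method = c("grid", "brute")) {
  d <- nn_distances(cells, from, to, compartment, method)
  d <- d[!is.na(d)]
  if (!length(d)) return(NA_real_)
  stats::median(d)
}

#' Within-radius interaction fraction
#'
#' Share of target-phenotype cells lying within `radius` micrometres
#' (boundary inclusive) of any anchor-phenotype cell on the slide:
#' `100 * |{t in target : min dist to anchor <= radius}| / |target|`.
#' For example, the percentage of PD-L1+ cells within 50 um of
#' CD8+PD-1+ T cells uses target = PD-L1+, anchor = CD8+PD-1+. An empty
#' anchor class gives 0% (with a warning); an empty target class gives
#' a missing value.
#'
#' @inheritParams nn_distances
#' @param target,anchor Phenotypes (def, name, or logical mask).
#' @param radius Interaction radius in micrometres (default 50, the
#'   conventional reach of T-cell-produced interferon-gamma signalling
#'   on neighboring cells, a 2-3 cell neighborhood).
#' @return Percent in \[0, 100\], or `NA` when the target class is empty.
#' @export
interaction_fraction <- function(cells, target, anchor, radius = 50,
                                 compartment = "both",
                                 method = c("grid", "brute")) {
  method <- match.arg(method)
  stopifnot(radius > 0)
  comp <- .in_compartment(cells, compartment)
  tg <- .spatial_subset(cells, target, comp)
  an <- .spatial_subset(cells, anchor, comp)
  if (!length(tg$x)) return(NA_real_)
  if (!length(an$x)) {
    warning("empty anchor class; interaction fraction is 0 by convention",
            call. = FALSE)
    return(0)
  }
  f <- if (method == "grid") .within_radius_grid else .within_radius_brute
  hits <- f(tg$x, tg$y, tg$id, an$x, an$y, an$id, radius)
  100 * sum(hits) / length(hits)
}

#' Per-specimen spatial interaction panel
#'
#' The slide-level spatial parameters of the analysis: interaction
#' fractions of PD-L1+ tumor cells and of all PD-L1+ cells with CD8+
#' and with CD8+PD-1+ T cells, of FoxP3+ Tregs with CD8+ and CD8+PD-1+
#' T cells, and the median nearest-neighbor distance from CD8+PD-1+
#' cells to PD-L1+ cells. Computed in the tumor compartment by default,
#' matching the reported analyses.
#'
#' @inheritParams interaction_fraction
#' @return Named numeric vector; entries are `NA`/0 per the conventions
#'   of [interaction_fraction()] when classes are empty.
#' @export
interaction_panel <- function(cells, radius = 50, compartment = "tumor",
                              method = c("grid", "brute")) {
  method <- match.arg(method)
  frac <- function(target, anchor)
    suppressWarnings(interaction_fraction(cells, target, anchor, radius,
                                          compartment, method))
  tag <- function(t, a) sprintf("frac_%s_within%g_of_%s", t, radius, a)
  out <- c(frac("PDL1_tumor", "CD8"), frac("PDL1", "CD8"),
           frac("PDL1_tumor", "CD8_PD1"), frac("PDL1", "CD8_PD1"),
           frac("FOXP3", "CD8"), frac("FOXP3", "CD8_PD1"),
           median_nn_distance(cells, "CD8_PD1", "PDL1", compartment, method))
  names(out) <- c(tag("PDL1tumor", "CD8"), tag("PDL1", "CD8"),
                  tag("PDL1tumor", "CD8PD1"), tag("PDL1", "CD8PD1"),
                  tag("FoxP3", "CD8"), tag("FoxP3", "CD8PD1"),
                  "median_nn_CD8PD1_to_PDL1")
  out
}

#' Per-specimen phenotype-fraction panel
#'
#' The slide-level population parameters: CD8+, FoxP3+, dysfunctional
#' (CD8+PD-1+) and terminally dysfunctional (CD8+PD-1+TOX+) fractions
#' out of total nucleated cells and out of CD8+ cells, the CD8/FoxP3
#' ratio, and PD-L1 positivity in Pax8+ tumor cells and combined.
#'
#' @inheritParams interaction_fraction
#' @return Named numeric vector.
#' @export
phenotype_panel <- function(cells, compartment = "tumor") {
  pf <- function(ph, den = "total_nucleated")
    suppressWarnings(population_fraction(cells, ph, den, compartment))
  c(pct_CD8 = pf("CD8"),
    pct_FOXP3 = pf("FOXP3"),
    ratio_CD8_FOXP3 = cd8_foxp3_ratio(cells, compartment),
    pct_CD8_PD1 = pf("CD8_PD1"),
    pct_CD8_PD1_TOX = pf("CD8_PD1_TOX"),
    pct_CD8_PD1_of_CD8 = pf("CD8_PD1", "CD8"),
    pct_CD8_PD1_TOX_of_CD8 = pf("CD8_PD1_TOX", "CD8"),
    pct_PDL1_tumor = pdl1_positivity(cells, "tumor_cells", compartment),
    pct_PDL1_all = pdl1_positivity(cells, "combined", compartment))
}

#' Build the patient-level biomarker matrix
#'
#' Computes the phenotype and spatial panels per specimen, then averages
#' specimens of the same patient with an unweighted mean (missing
#' specimen values dropped).
#'
#' @param cells_list List of [cell_table] objects.
#' @param manifest Data frame with `specimen_id`, `patient_id`.
#' @param radius Interaction radius in micrometres.
#' @param compartment Analysis compartment (default `"tumor"`).
#' @return Data frame, one row per patient with a `patient_id` column
#'   followed by the panel parameters (percent or micrometres).
#' @export
build_biomarker_matrix <- function(cells_list, manifest, radius = 50,
                                   compartment = "tumor") {
  per_spec <- lapply(cells_list, function(ct)
    c(phenotype_panel(ct, compartment),
      interaction_panel(ct, radius, compartment)))
  spec_ids <- vapply(cells_list, specimen_id, character(1))
  pats <- manifest$patient_id[match(spec_ids, manifest$specimen_id)]
  keep <- !is.na(pats)
  per_spec <- per_spec[keep]; pats <- pats[keep]
  params <- names(per_spec[[1L]])
  rows <- lapply(unique(pats), function(p) {
    m <- do.call(rbind, per_spec[pats == p])
    vapply(params, function(cl) patient_average(m[, cl]), numeric(1))
  })
  out <- as.data.frame(do.call(rbind, rows))
  out <- cbind(patient_id = unique(pats), out)
  rownames(out) <- NULL
  out
}
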