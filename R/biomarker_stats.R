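# Group-association statistics for the biomarker analyses. All of these
# are authored here (the standard library routines serve only as
# independent cross-checks in the test suite). No multiple-testing
# adjustment is applied anywhere, matching the reporting convention of
# the exploratory analyses this pipeline reproduces.

#' Construct a 2x2 contingency table
#'
#' Rows are biomarker high/low (test positive/negative), columns are
#' clinical benefit / no benefit: `a` = high & benefit, `b` = high & no
#' benefit, `c` = low & benefit, `d` = low & no benefit.
#'
#' @param a,b,c,d Non-negative integer counts, `a + b + c + d > 0`.
#' @return A `two_by_two` object.
#' @export
two_by_two <- function(a, b, c, d) {
  counts <- c(a = a, b = b, c = c, d = d)
  if (any(counts < 0) || any(counts != round(counts)))
    stop("two_by_two: counts must be non-negative integers", call. = FALSE)
  if (sum(counts) == 0) stop("two_by_two: empty table", call. = FALSE)
  structure(as.list(counts), class = "two_by_two")
}

#' Mann-Whitney rank test
#'
#' Two-sample rank test with midrank handling of ties. The two-sided
#' p-value is exact by complete enumeration of group assignments when
#' the smaller group has at most 8 observations and there are no ties;
#' otherwise a normal approximation with tie-corrected variance and
#' continuity correction is used. The exact two-sided p is twice the
#' smaller tail, capped at 1.
#'
#' @param x,y Numeric vectors (both non-empty).
#' @return List with `U` (statistic for `x`), `p.value`, and `method`
#'   (`"exact"` or `"normal"`).
#' @export
mann_whitney <- function(x, y) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (!length(x) || !length(y))
    stop("mann_whitney: a group is empty", call. = FALSE)
  nx <- length(x); ny <- length(y); n <- nx + ny
  pooled <- c(x, y)
  rk <- rank(pooled)
  U <- sum(rk[seq_len(nx)]) - nx * (nx + 1) / 2
  ties <- any(duplicated(pooled))
  if (min(nx, ny) <= 8 && !ties) {
    combs <- utils::combn(n, nx)
    ssum <- colSums(matrix(rk[combs], nrow = nx))
    Us <- ssum - nx * (nx + 1) / 2
    p_lo <- mean(Us <= U); p_hi <- mean(Us >= U)
    p <- min(1, 2 * min(p_lo, p_hi))
    return(list(U = U, p.value = p, method = "exact"))
  }
  mu <- nx * ny / 2
  tie_tab <- table(pooled)
  tie_term <- sum(tie_tab^3 - tie_tab) / (n * (n - 1))
  v <- nx * ny / 12 * ((n + 1) - tie_term)
  if (v <= 0) return(list(U = U, p.value = 1, method = "normal"))
  z <- (U - mu - sign(U - mu) * 0.5) / sqrt(v)
  p <- min(1, 2 * stats::pnorm(-abs(z)))
  list(U = U, p.value = p, method = "normal")
}

#' Fisher exact test (two-sided, minimum-likelihood rule)
#'
#' Enumerates all 2x2 tables with the observed margins under the
#' hypergeometric null; the two-sided p-value sums the probabilities of
#' every table whose point probability does not exceed that of the
#' observed table. Any zero margin gives p = 1.
#'
#' @param t A [two_by_two].
#' @return Two-sided p-value.
#' @export
fisher_exact <- function(t) {
  stopifnot(inherits(t, "two_by_two"))
  a <- t$a; b <- t$b; c <- t$c; d <- t$d
  m1 <- a + b; m2 <- c + d; k1 <- a + c; k2 <- b + d
  if (m1 == 0 || m2 == 0 || k1 == 0 || k2 == 0) return(1)
  lo <- max(0L, k1 - m2); hi <- min(m1, k1)
  ks <- lo:hi
  probs <- stats::dhyper(ks, m1, m2, k1)
  p_obs <- stats::dhyper(a, m1, m2, k1)
  min(1, sum(probs[probs <= p_obs * (1 + 1e-7)]))
}

#' Pearson chi-square test on a 2x2 table
#'
#' Statistic `n (ad - bc)^2 / ((a+b)(c+d)(a+c)(b+d))` with 1 degree of
#' freedom; Yates continuity correction optional. A zero margin yields
#' statistic 0 and p = 1 with a warning.
#'
#' @param t A [two_by_two].
#' @param yates Apply the continuity correction (default `FALSE`).
#' @return List with `statistic` and `p.value`.
#' @export
chi_square <- function(t, yates = FALSE) {
  stopifnot(inherits(t, "two_by_two"))
  a <- t$a; b <- t$b; c <- t$c; d <- t$d
  n <- a + b + c + d
  denom <- (a + b) * (c + d) * (a + c) * (b + d)
  if (denom == 0) {
    warning("zero margin; chi-square undefined, returning p = 1",
            call. = FALSE)
    return(list(statistic = 0, p.value = 1))
  }
  num <- abs(a * d - b * c)
  if (yates) num <- max(0, num - n / 2)
  stat <- n * num^2 / denom
  list(statistic = stat,
       p.value = stats::pchisq(stat, df = 1, lower.tail = FALSE))
}

#' Diagnostic metrics of a biomarker dichotomization
#'
#' Standard 2x2 definitions with biomarker-high as test-positive and
#' clinical benefit as the condition: sensitivity `a/(a+c)`, specificity
#' `d/(b+d)`, positive predictive value `a/(a+b)`, negative predictive
#' value `d/(c+d)`. A metric with a zero denominator is missing.
#'
#' @param t A [two_by_two].
#' @return Named numeric vector (percent): `sensitivity`, `specificity`,
#'   `ppv`, `npv`.
#' @export
diagnostics <- function(t) {
  stopifnot(inherits(t, "two_by_two"))
  safe <- function(num, den) if (den == 0) NA_real_ else 100 * num / den
  c(sensitivity = safe(t$a, t$a + t$c),
    specificity = safe(t$d, t$b + t$d),
    ppv = safe(t$a, t$a + t$b),
    npv = safe(t$d, t$c + t$d))
}

#' Bottom-tertile cutoff
#'
#' The 33 1/3rd percentile by linear interpolation of order statistics
#' (for sorted values `v` and `h = (n-1)/3`, the cutoff is
#' `v[floor(h)+1] + (h - floor(h)) * (v[floor(h)+2] - v[floor(h)+1])`).
#' Downstream dichotomization calls a value "high" iff it exceeds the
#' cutoff. The rule, not any particular cutoff value, is the contract:
#' published cutoffs are data-derived.
#'
#' @param values Numeric vector, at least 3 non-missing.
#' @return The cutoff. If all values are equal the split is degenerate
#'   (every value "low") and a warning is raised.
#' @export
bottom_tertile_cutoff <- function(values) {
  v <- sort(values[!is.na(values)])
  n <- length(v)
  if (n < 3) stop("bottom_tertile_cutoff: need >= 3 non-missing values",
                  call. = FALSE)
  if (v[1] == v[n])
    warning("all values equal; tertile split is degenerate", call. = FALSE)
  h <- (n - 1) / 3
  lo <- floor(h)
  if (lo + 1 >= n) return(v[n])
  v[lo + 1] + (h - lo) * (v[lo + 2] - v[lo + 1])
}

#' Dichotomize values at a cutoff
#'
#' @param values Numeric vector.
#' @param cutoff Cutoff value; "high" iff strictly greater.
#' @return Logical vector (`NA` propagated).
#' @export
dichotomize_high <- function(values, cutoff) values > cutoff

# pairwise-complete Pearson correlation by the covariance formula
.pearson_pairwise <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  if (sum(ok) < 3) return(NA_real_)
  x <- x[ok]; y <- y[ok]
  sx <- x - mean(x); sy <- y - mean(y)
  den <- sqrt(sum(sx^2) * sum(sy^2))
  if (den == 0) return(NA_real_)
  sum(sx * sy) / den
}

# average-linkage (UPGMA) agglomeration over a distance matrix,
# returning the leaf order of the resulting dendrogram
.upgma_order <- function(D) {
  p <- nrow(D)
  active <- as.list(seq_len(p))    # leaf members per cluster
  sizes <- rep(1, p)
  d <- D
  diag(d) <- Inf
  while (length(active) > 1) {
    idx <- which(d == min(d), arr.ind = TRUE)[1, ]
    i <- min(idx); j <- max(idx)
    new_members <- c(active[[i]], active[[j]])
    ni <- sizes[i]; nj <- sizes[j]
    new_d <- (ni * d[i, ] + nj * d[j, ]) / (ni + nj)
    keep <- setdiff(seq_along(active), c(i, j))
    d <- rbind(cbind(d[keep, keep, drop = FALSE], new_d[keep]),
               c(new_d[keep], Inf))
    active <- c(active[keep], list(new_members))
    sizes <- c(sizes[keep], ni + nj)
  }
  active[[1]]
}

#' Correlation matrix and clustering of biomarker parameters
#'
#' Pairwise-complete Pearson correlations between all parameter columns,
#' then agglomerative clustering on distance `1 - r` with average
#' linkage; the dendrogram leaf order is returned so correlated
#' parameters can be displayed adjacently. Constant columns (zero
#' variance) cannot be correlated; they are excluded from clustering
#' with a warning.
#'
#' @param m Numeric matrix or data.frame of parameter columns (at least
#'   2), rows are patients; a `patient_id` column is ignored.
#' @return List with `r` (correlation matrix), `order` (leaf order as
#'   column names), and `dropped` (excluded constant columns).
#' @export
correlation_cluster <- function(m) {
  m <- as.data.frame(m)
  m$patient_id <- NULL
  m <- as.matrix(m)
  if (ncol(m) < 2) stop("need >= 2 parameters", call. = FALSE)
  const <- apply(m, 2, function(v) {
    v <- v[!is.na(v)]; length(v) < 2 || stats::var(v) == 0
  })
  dropped <- colnames(m)[const]
  if (length(dropped))
    warning("constant column(s) excluded from clustering: ",
            paste(dropped, collapse = ", "), call. = FALSE)
  p <- ncol(m)
  r <- matrix(NA_real_, p, p, dimnames = list(colnames(m), colnames(m)))
  diag(r) <- 1
  for (i in seq_len(p)) for (j in seq_len(p)) if (i < j)
    r[i, j] <- r[j, i] <- .pearson_pairwise(m[, i], m[, j])
  keep <- which(!const)
  ord <- if (length(keep) >= 2) {
    D <- 1 - r[keep, keep, drop = FALSE]
    D[is.na(D)] <- 2   # uncorrelatable pairs treated as maximally distant
    colnames(m)[keep][.upgma_order(D)]
  } else colnames(m)[keep]
  list(r = r, order = ord, dropped = dropped)
}

#' Logistic regression by iteratively reweighted least squares
#'
#' Maximum-likelihood logistic fit of a binary outcome on a covariate
#' matrix (intercept added). Convergence when the largest coefficient
#' change falls below `tol` or after `max_iter` iterations. Complete
#' separation is detected from a diverging coefficient norm and flagged
#' in the result rather than silently returned.
#'
#' @param X Numeric matrix or data.frame of covariates (no intercept
#'   column).
#' @param y Binary outcome: logical, 0/1, or a two-level factor.
#' @param max_iter Maximum IRLS iterations (default 100).
#' @param tol Convergence tolerance on coefficients (default 1e-8).
#' @return List with `coefficients` (named, `(Intercept)` first),
#'   `fitted` (probabilities), `converged`, `separated`, `iterations`,
#'   and `se` (asymptotic standard errors, `NA` when separated).
#' @export
logistic_fit <- function(X, y, max_iter = 100, tol = 1e-8) {
  X <- as.matrix(as.data.frame(X))
  storage.mode(X) <- "double"
  if (is.factor(y)) y <- as.integer(y) - 1L
  y <- as.numeric(y)
  stopifnot(all(y %in% c(0, 1)), nrow(X) == length(y))
  if (length(y) < 6) stop("logistic_fit: need >= 6 observations",
                          call. = FALSE)
  if (length(unique(y)) < 2)
    stop("logistic_fit: outcome has a single class", call. = FALSE)
  Xd <- cbind(`(Intercept)` = 1, X)
  p <- ncol(Xd)
  beta <- rep(0, p)
  converged <- FALSE; separated <- FALSE; it <- 0
  for (it in seq_len(max_iter)) {
    eta <- drop(Xd %*% beta)
    mu <- 1 / (1 + exp(-eta))
    w <- mu * (1 - mu)
    w <- pmax(w, 1e-12)
    z <- eta + (y - mu) / w
    XtWX <- crossprod(Xd, Xd * w)
    beta_new <- tryCatch(solve(XtWX, crossprod(Xd, w * z)),
                         error = function(e) NULL)
    if (is.null(beta_new)) { separated <- TRUE; break }
    beta_new <- drop(beta_new)
    delta <- max(abs(beta_new - beta))
    beta <- beta_new
    if (sqrt(sum(beta^2)) > 1e3) { separated <- TRUE; break }
    if (delta < tol) { converged <- TRUE; break }
  }
  names(beta) <- colnames(Xd)
  eta <- drop(Xd %*% beta)
  fitted <- 1 / (1 + exp(-eta))
  # under complete separation the coefficient norm diverges instead of
  # converging; flag it when the linear predictor has escaped to the
  # saturated region without meeting the coefficient tolerance
  if (!converged && max(abs(eta)) > 10) separated <- TRUE
  se <- rep(NA_real_, p)
  if (!separated) {
    w <- pmax(fitted * (1 - fitted), 1e-12)
    cov <- tryCatch(solve(crossprod(Xd, Xd * w)), error = function(e) NULL)
    if (!is.null(cov)) se <- sqrt(diag(cov))
  }
  names(se) <- colnames(Xd)
  list(coefficients = beta, fitted = fitted, converged = converged,
       separated = separated, iterations = it, se = se)
}

#' ROC curve and AUC
#'
#' AUC by the rank (Mann-Whitney) formulation with midranks, so tied
#' scores count one half; ROC points by a sweep over the distinct score
#' thresholds (classification rule: positive iff score >= threshold).
#' Trapezoidal integration of the returned points equals the rank AUC.
#'
#' @param scores Numeric scores (higher = more likely positive).
#' @param labels Binary labels (logical, 0/1 or two-level factor); both
#'   classes must be present.
#' @return List with `auc` and `points` (data.frame `threshold`, `fpr`,
#'   `tpr`, including the (0,0) and (1,1) endpoints).
#' @export
roc_auc <- function(scores, labels) {
  if (is.factor(labels)) labels <- as.integer(labels) - 1L
  labels <- as.numeric(labels)
  stopifnot(all(labels %in% c(0, 1)), length(scores) == length(labels))
  npos <- sum(labels == 1); nneg <- sum(labels == 0)
  if (npos == 0 || nneg == 0)
    stop("roc_auc: both classes must be present", call. = FALSE)
  rk <- rank(scores)
  auc <- (sum(rk[labels == 1]) - npos * (npos + 1) / 2) / (npos * nneg)
  thr <- sort(unique(scores), decreasing = TRUE)
  tpr <- vapply(thr, function(t) sum(scores >= t & labels == 1) / npos,
                numeric(1))
  fpr <- vapply(thr, function(t) sum(scores >= t & labels == 0) / nneg,
                numeric(1))
  points <- data.frame(threshold = c(Inf, thr), fpr = c(0, fpr),
                       tpr = c(0, tpr))
  if (points$fpr[nrow(points)] < 1 || points$tpr[nrow(points)] < 1)
    points <- rbind(points, data.frame(threshold = -Inf, fpr = 1, tpr = 1))
  list(auc = auc, points = points)
}
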