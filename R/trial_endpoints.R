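# Endpoint derivation and design statistics for a single-arm phase 2
# trial: simplified RECIST 1.1 target-lesion response, ORR/DCR/PFS24
# with exact binomial intervals, product-limit survival summaries, and
# exact Simon two-stage operating characteristics.

#' Construct a Simon two-stage design
#'
#' Decision rule of a two-stage single-arm design: enroll `n1` evaluable
#' patients in stage 1 and continue iff successes exceed the futility
#' bound `r1` (i.e. at least `r1 + 1`); after `n` total, declare the
#' regimen promising iff total successes exceed `r` (at least `r + 1`).
#'
#' @param n1 Stage-1 evaluable count.
#' @param r1 Stage-1 futility bound (continue iff successes >= r1 + 1).
#' @param n Total evaluable count.
#' @param r Final bound (promising iff successes >= r + 1).
#' @param p0 Null (non-promising) success rate.
#' @param p1 Alternative (promising) success rate.
#' @return A `two_stage_design`.
#' @export
two_stage_design <- function(n1, r1, n, r, p0, p1) {
  if (!(0 <= r1 && r1 < n1 && n1 <= n))
    stop("invalid design: need 0 <= r1 < n1 <= n", call. = FALSE)
  if (!(r1 <= r && r < n))
    stop("invalid design: need r1 <= r < n", call. = FALSE)
  if (!(0 < p0 && p0 < p1 && p1 < 1))
    stop("invalid design: need 0 < p0 < p1 < 1", call. = FALSE)
  structure(list(n1 = n1, r1 = r1, n = n, r = r, p0 = p0, p1 = p1),
            class = "two_stage_design")
}

#' Exact operating characteristics of a Simon two-stage design
#'
#' Exact binomial enumeration (no normal approximation): the
#' probability of declaring the regimen promising at true success rate
#' `p` is the sum over stage-1 success counts `s1 = r1+1 .. n1` of
#' `Bin(s1; n1, p) * P(stage-2 successes >= r+1-s1; n-n1, p)`; early
#' stopping is `P(s1 <= r1)`; the expected sample size is
#' `n1 + (1 - P(early stop)) (n - n1)`. The attained type I error is
#' `prob_promising` at `p = p0`; the attained type II error is
#' `1 - prob_promising` at `p = p1`.
#'
#' @param design A [two_stage_design].
#' @param p True success rate.
#' @return List with `prob_promising`, `prob_early_stop`, `expected_n`.
#' @export
simon_oc <- function(design, p) {
  stopifnot(inherits(design, "two_stage_design"), p >= 0, p <= 1)
  n1 <- design$n1; r1 <- design$r1; n <- design$n; r <- design$r
  n2 <- n - n1
  s1 <- (r1 + 1):n1
  need2 <- pmax(0, r + 1 - s1)
  p2 <- ifelse(need2 == 0, 1,
               stats::pbinom(need2 - 1, n2, p, lower.tail = FALSE))
  promising <- sum(stats::dbinom(s1, n1, p) * p2)
  early <- stats::pbinom(r1, n1, p)
  list(prob_promising = promising, prob_early_stop = early,
       expected_n = n1 + (1 - early) * n2)
}

#' Best overall response from target-lesion sums
#'
#' Simplified RECIST 1.1 target-lesion rules, per timepoint: complete
#' response when the sum is 0; partial response at a decrease of at
#' least 30% from baseline; progression at an increase of at least 20%
#' from the nadir (smallest sum so far, baseline included) that is also
#' at least 5 mm absolute; stable disease otherwise. Best overall
#' response is CR if ever achieved, else PR if achieved before
#' progression, else PD if progression occurred, else SD; no
#' post-baseline assessment gives NE. Nodal short-axis, non-target and
#' new-lesion rules and response confirmation are not modeled.
#'
#' @param baseline_sum Baseline sum of target-lesion diameters in mm
#'   (> 0).
#' @param followup_sums Post-baseline sums in assessment order (mm).
#' @return One of `"CR"`, `"PR"`, `"SD"`, `"PD"`, `"NE"`.
#' @export
classify_bor <- function(baseline_sum, followup_sums) {
  if (is.na(baseline_sum) || baseline_sum <= 0)
    stop("classify_bor: baseline sum must be positive", call. = FALSE)
  followup_sums <- followup_sums[!is.na(followup_sums)]
  if (any(followup_sums < 0))
    stop("classify_bor: negative lesion sum", call. = FALSE)
  if (!length(followup_sums)) return("NE")
  nadir <- baseline_sum
  seen <- character(0)
  for (s in followup_sums) {
    if (s >= nadir * 1.2 && s - nadir >= 5) { seen <- c(seen, "PD"); break }
    if (s == 0) seen <- c(seen, "CR")
    else if (s <= baseline_sum * 0.7) seen <- c(seen, "PR")
    else seen <- c(seen, "SD")
    nadir <- min(nadir, s)
  }
  if ("CR" %in% seen) "CR"
  else if ("PR" %in% seen) "PR"
  else if ("PD" %in% seen) "PD"
  else "SD"
}

#' Objective response and disease control rates
#'
#' ORR = (CR + PR) / evaluable, DCR = (CR + PR + SD) / evaluable, with
#' non-evaluable (NE) patients excluded from the denominator per the
#' evaluability rule (at least one dose and one post-baseline
#' assessment).
#'
#' @param bors Character vector of best overall responses.
#' @return List with `orr` and `dcr` (percent), `n_evaluable`, and
#'   `counts` (table over CR/PR/SD/PD/NE).
#' @export
response_rates <- function(bors) {
  bad <- setdiff(unique(bors), c("CR", "PR", "SD", "PD", "NE"))
  if (length(bad)) stop("unknown BOR categories: ",
                        paste(bad, collapse = ", "), call. = FALSE)
  counts <- table(factor(bors, levels = c("CR", "PR", "SD", "PD", "NE")))
  n_eval <- sum(counts[c("CR", "PR", "SD", "PD")])
  if (n_eval == 0) stop("no evaluable patients", call. = FALSE)
  list(orr = 100 * sum(counts[c("CR", "PR")]) / n_eval,
       dcr = 100 * sum(counts[c("CR", "PR", "SD")]) / n_eval,
       n_evaluable = n_eval, counts = counts)
}

#' Clopper-Pearson exact binomial confidence interval
#'
#' Exact interval from beta-distribution quantiles. For the two-sided
#' interval at level `level`, the lower bound is the `(1-level)/2` beta
#' quantile with shape `(x, n-x+1)` (0 when `x = 0`) and the upper
#' bound the `1-(1-level)/2` quantile with shape `(x+1, n-x)` (1 when
#' `x = n`). A one-sided bound at level `level` uses the full `1-level`
#' tail on one side, so the one-sided 97.5% lower bound coincides with
#' the two-sided 95% lower bound.
#'
#' @param x Successes, `0 <= x <= n`.
#' @param n Trials, `n >= 1`.
#' @param level Confidence level in (0, 1), default 0.95.
#' @param sided `"two"`, `"lower_one"` (interval `[lower, 1]`) or
#'   `"upper_one"` (`[0, upper]`).
#' @return List with `lower` and `upper` as proportions in \[0, 1\].
#' @export
clopper_pearson <- function(x, n, level = 0.95,
                            sided = c("two", "lower_one", "upper_one")) {
  sided <- match.arg(sided)
  if (!(n >= 1 && x >= 0 && x <= n))
    stop("clopper_pearson: need 0 <= x <= n, n >= 1", call. = FALSE)
  if (!(level > 0 && level < 1))
    stop("clopper_pearson: invalid level", call. = FALSE)
  alpha <- switch(sided, two = (1 - level) / 2, 1 - level)
  lower <- if (x == 0) 0 else stats::qbeta(alpha, x, n - x + 1)
  upper <- if (x == n) 1 else stats::qbeta(1 - alpha, x + 1, n - x)
  switch(sided,
         two = list(lower = lower, upper = upper),
         lower_one = list(lower = lower, upper = 1),
         upper_one = list(lower = 0, upper = upper))
}

#' Classify patients for the 24-week progression-free endpoint
#'
#' A patient has clinical benefit iff progression-free and alive at 24
#' weeks (`weeks_to_months(24)` = 5.5195 months). Patients lost to
#' follow-up or dead before the 24-week assessment are counted as
#' events (no benefit), per the trial's evaluability rule.
#'
#' @param pfs_months PFS time in months (to progression/death or last
#'   follow-up).
#' @param pfs_event Logical event flags (TRUE = progression or death).
#' @return List with `benefit` and `no_benefit` counts and the per-
#'   patient logical vector `is_benefit`.
#' @export
pfs24_classify <- function(pfs_months, pfs_event) {
  stopifnot(length(pfs_months) == length(pfs_event))
  is_benefit <- pfs_months >= .PFS24_MONTHS
  list(benefit = sum(is_benefit), no_benefit = sum(!is_benefit),
       is_benefit = is_benefit)
}

#' Kaplan-Meier product-limit estimate
#'
#' Hand-computed product-limit estimator with Greenwood variance.
#' Landmark confidence intervals use the log(-log) transform. The
#' median is the smallest observed time at which the estimate drops to
#' 0.5 or below; when the curve stays above 0.5 the median is not
#' reached (`NA`). Median confidence limits are the smallest times at
#' which the upper (resp. lower) pointwise band drops to 0.5 or below
#' (band-crossing rule).
#'
#' @param times Follow-up times (months), non-negative.
#' @param events Logical event flags (FALSE = censored).
#' @param landmark Optional time at which to report a survival rate
#'   with confidence interval.
#' @param conf_level Confidence level (default 0.95).
#' @return List with `curve` (data.frame `time`, `n_risk`, `n_event`,
#'   `n_censor`, `surv`, `se`, `lower`, `upper`), `median`,
#'   `median_ci`, and (when requested) `landmark` =
#'   `list(time, surv, lower, upper)`.
#' @export
km_estimate <- function(times, events, landmark = NULL, conf_level = 0.95) {
  if (any(times < 0)) stop("km_estimate: negative time", call. = FALSE)
  stopifnot(length(times) == length(events), length(times) >= 1)
  events <- as.logical(events)
  ut <- sort(unique(times))
  n_risk <- vapply(ut, function(t) sum(times >= t), numeric(1))
  n_event <- vapply(ut, function(t) sum(times == t & events), numeric(1))
  n_censor <- vapply(ut, function(t) sum(times == t & !events), numeric(1))
  surv <- cumprod(1 - n_event / n_risk)
  # Greenwood: var(S) = S^2 * cumsum(d / (n (n - d)))
  gterm <- ifelse(n_risk > n_event, n_event / (n_risk * (n_risk - n_event)), 0)
  gsum <- cumsum(gterm)
  se <- surv * sqrt(gsum)
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  # log(-log) interval: S^exp(+-z*se(log(-log S)))
  ci <- function(s, g) {
    if (s <= 0 || s >= 1 || g <= 0) return(c(NA_real_, NA_real_))
    se_ll <- sqrt(g) / abs(log(s))
    c(s^exp(z * se_ll), s^exp(-z * se_ll))
  }
  bounds <- t(vapply(seq_along(ut), function(i) ci(surv[i], gsum[i]),
                     numeric(2)))
  curve <- data.frame(time = ut, n_risk = n_risk, n_event = n_event,
                      n_censor = n_censor, surv = surv, se = se,
                      lower = bounds[, 1], upper = bounds[, 2])
  med_idx <- which(surv <= 0.5)
  median_t <- if (length(med_idx)) ut[min(med_idx)] else NA_real_
  up_idx <- which(!is.na(curve$upper) & curve$upper <= 0.5 |
                    surv == 0)
  lo_idx <- which(!is.na(curve$lower) & curve$lower <= 0.5 | surv == 0)
  median_ci <- c(lower = if (length(lo_idx)) ut[min(lo_idx)] else NA_real_,
                 upper = if (length(up_idx)) ut[min(up_idx)] else NA_real_)
  out <- list(curve = curve, median = median_t, median_ci = median_ci)
  if (!is.null(landmark)) {
    idx <- which(ut <= landmark)
    if (!length(idx)) {
      out$landmark <- list(time = landmark, surv = 1, lower = NA_real_,
                           upper = NA_real_)
    } else {
      i <- max(idx)
      b <- ci(surv[i], gsum[i])
      out$landmark <- list(time = landmark, surv = surv[i],
                           lower = b[1], upper = b[2])
    }
  }
  out
}
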