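test_that("Mann-Whitney exact path matches full enumeration and symmetry", {
  res <- mann_whitney(1:3, 4:6)
  expect_equal(res$method, "exact")
  expect_equal(res$U, 0)
  expect_equal(res$p.value, 0.1)  # 2 * 1/20 orderings
  # swapping groups maps U -> nx*ny - U and leaves p unchanged
  res2 <- mann_whitney(4:6, 1:3)
  expect_equal(res2$U, 9)
  expect_equal(res2$p.value, res$p.value)
  # identical multisets (ties force the approximate path): p = 1
  res3 <- mann_whitney(c(1, 2, 3), c(1, 2, 3))
  expect_equal(res3$method, "normal")
  expect_equal(res3$p.value, 1)
})

test_that("Mann-Whitney agrees with the standard-library cross-check", {
  set.seed(61)
  for (i in 1:10) {
    x <- rnorm(sample(3:8, 1)); y <- rnorm(sample(3:8, 1), mean = 0.5)
    ours <- mann_whitney(x, y)
    ref <- wilcox.test(x, y, exact = TRUE)
    expect_equal(ours$U, unname(ref$statistic))
    expect_equal(ours$p.value, ref$p.value, tolerance = 1e-10)
  }
  for (i in 1:10) {  # tied / large-sample normal path
    x <- sample(1:6, 15, replace = TRUE)
    y <- sample(2:8, 18, replace = TRUE)
    ours <- mann_whitney(x, y)
    ref <- wilcox.test(x, y, exact = FALSE, correct = TRUE)
    expect_equal(ours$p.value, ref$p.value, tolerance = 1e-8)
  }
})

test_that("Fisher exact reproduces the benefit-group table and the oracle", {
  # 6/19 vs 0/14 mutated: printed two-sided p = 0.027
  expect_equal(fisher_exact(two_by_two(6, 13, 0, 14)), 0.0272, tolerance = 2e-3)
  # zero margin degenerates to p = 1
  expect_equal(fisher_exact(two_by_two(0, 0, 5, 7)), 1)
  set.seed(62)
  for (i in 1:30) {
    t <- two_by_two(rpois(1, 4), rpois(1, 4), rpois(1, 4), rpois(1, 4))
    if (sum(unlist(t)) == 0) next
    ref <- fisher.test(matrix(unlist(t), 2, byrow = TRUE))$p.value
    expect_equal(fisher_exact(t), ref, tolerance = 1e-7)
  }
})

test_that("chi-square follows the closed form and the textbook oracle", {
  expect_equal(chi_square(two_by_two(5, 5, 5, 5))$statistic, 0)
  expect_equal(chi_square(two_by_two(5, 5, 5, 5))$p.value, 1)
  expect_equal(chi_square(two_by_two(10, 0, 0, 10))$statistic, 20)
  expect_warning(res <- chi_square(two_by_two(0, 0, 5, 7)), "zero margin")
  expect_equal(res$p.value, 1)
  set.seed(63)
  for (i in 1:50) {
    cnt <- rpois(4, 6) + 1
    t <- two_by_two(cnt[1], cnt[2], cnt[3], cnt[4])
    # direct formula evaluated independently
    n <- sum(cnt)
    stat <- n * (cnt[1] * cnt[4] - cnt[2] * cnt[3])^2 /
      ((cnt[1] + cnt[2]) * (cnt[3] + cnt[4]) *
         (cnt[1] + cnt[3]) * (cnt[2] + cnt[4]))
    expect_equal(chi_square(t)$statistic, stat)
    ref <- suppressWarnings(
      chisq.test(matrix(cnt, 2, byrow = TRUE), correct = FALSE))
    expect_equal(chi_square(t)$statistic, unname(ref$statistic))
    refy <- suppressWarnings(
      chisq.test(matrix(cnt, 2, byrow = TRUE), correct = TRUE))
    expect_equal(chi_square(t, yates = TRUE)$statistic,
                 unname(refy$statistic))
  }
})

test_that("2x2 diagnostics match direct counts", {
  expect_equal(unname(diagnostics(two_by_two(10, 0, 0, 10))),
               rep(100, 4))
  expect_equal(diagnostics(two_by_two(0, 10, 10, 0))[["sensitivity"]], 0)
  set.seed(64)
  for (i in 1:20) {
    cnt <- rpois(4, 5) + 1
    d <- diagnostics(two_by_two(cnt[1], cnt[2], cnt[3], cnt[4]))
    expect_equal(d[["sensitivity"]], 100 * cnt[1] / (cnt[1] + cnt[3]))
    expect_equal(d[["specificity"]], 100 * cnt[4] / (cnt[2] + cnt[4]))
    expect_equal(d[["ppv"]], 100 * cnt[1] / (cnt[1] + cnt[2]))
    expect_equal(d[["npv"]], 100 * cnt[4] / (cnt[3] + cnt[4]))
  }
})

test_that("bottom-tertile cutoff interpolates order statistics", {
  # values 1..9: h = 8/3, cutoff = 3 + 2/3
  cut <- bottom_tertile_cutoff(1:9)
  expect_equal(cut, 3 + 2 / 3, tolerance = 1e-12)
  expect_equal(sum(1:9 <= cut), 3)
  expect_equal(cut, unname(quantile(1:9, 1 / 3, type = 7)))
  # permutation invariance
  expect_equal(bottom_tertile_cutoff(sample(1:9)), cut)
  expect_warning(bottom_tertile_cutoff(rep(4, 5)), "degenerate")
  expect_error(bottom_tertile_cutoff(c(1, 2)), ">= 3")
  set.seed(65)
  v <- rnorm(25)
  expect_equal(bottom_tertile_cutoff(v),
               unname(quantile(v, 1 / 3, type = 7)))
})

test_that("correlation and clustering behave on constructed columns", {
  set.seed(66)
  m <- data.frame(a = rnorm(30), b = rnorm(30), c = rnorm(30))
  m$a2 <- m$a                 # duplicate -> r = 1, merged adjacently
  m$neg_b <- -m$b             # negation -> r = -1
  res <- correlation_cluster(m)
  expect_equal(res$r["a", "a2"], 1)
  expect_equal(res$r["b", "neg_b"], -1)
  expect_equal(abs(match("a", res$order) - match("a2", res$order)), 1)
  # r matches the direct covariance formula
  ref <- cor(as.matrix(m), use = "pairwise.complete.obs")
  expect_equal(res$r, ref, tolerance = 1e-12)
  m$const <- 5
  expect_warning(res2 <- correlation_cluster(m), "constant")
  expect_false("const" %in% res2$order)
})

test_that("logistic IRLS matches glm and detects separation", {
  set.seed(67)
  n <- 200
  X <- cbind(x1 = rnorm(n), x2 = rnorm(n))
  eta <- -0.4 + 0.9 * X[, 1] - 0.7 * X[, 2]
  y <- rbinom(n, 1, plogis(eta))
  fit <- logistic_fit(X, y)
  ref <- glm(y ~ X, family = binomial())
  expect_true(fit$converged)
  expect_false(fit$separated)
  expect_equal(unname(fit$coefficients), unname(coef(ref)),
               tolerance = 1e-6)
  expect_equal(unname(fit$fitted), unname(fitted(ref)), tolerance = 1e-6)
  # intercept-only data with 25% positives: all fitted probabilities 0.25
  y2 <- rep(c(1, 0, 0, 0), 5)
  fit2 <- logistic_fit(matrix(nrow = 20, ncol = 0), y2)
  expect_equal(unname(fit2$fitted), rep(0.25, 20), tolerance = 1e-8)
  # complete separation is flagged, not silently returned
  Xs <- matrix(c(1:5, 11:15), ncol = 1)
  ys <- c(rep(0, 5), rep(1, 5))
  fit3 <- logistic_fit(Xs, ys)
  expect_true(fit3$separated)
  expect_error(logistic_fit(X, rep(1, n)), "single class")
})

test_that("logistic slopes shrink to zero under permuted labels", {
  set.seed(68)
  n <- 1000
  X <- cbind(x1 = rnorm(n), x2 = rnorm(n))
  y <- sample(rep(0:1, n / 2))  # labels independent of X
  fit <- logistic_fit(X, y)
  for (j in 2:3)
    expect_lt(abs(fit$coefficients[j]), 3 * fit$se[j] + 1e-9)
})

test_that("ROC/AUC rank formulation agrees with trapezoidal integration", {
  # perfect separation
  expect_equal(roc_auc(c(1, 2, 3, 10, 11, 12),
                       c(0, 0, 0, 1, 1, 1))$auc, 1)
  set.seed(69)
  # null limit: labels independent of scores
  big <- roc_auc(rnorm(4000), rbinom(4000, 1, 0.5))
  expect_equal(big$auc, 0.5, tolerance = 0.05)
  trap <- function(p) sum(diff(p$fpr) * (head(p$tpr, -1) + tail(p$tpr, -1)) / 2)
  for (i in 1:100) {
    n <- sample(10:40, 1)
    scores <- sample(1:8, n, replace = TRUE)  # ties on purpose
    labels <- rbinom(n, 1, 0.5)
    if (length(unique(labels)) < 2) next
    r <- roc_auc(scores, labels)
    expect_equal(trap(r$points), r$auc, tolerance = 1e-12)
  }
  # complementarity without ties
  sc <- rnorm(50); lb <- rbinom(50, 1, 0.5)
  if (length(unique(lb)) == 2)
    expect_equal(roc_auc(sc, lb)$auc + roc_auc(-sc, lb)$auc, 1)
})
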