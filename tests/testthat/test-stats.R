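# Agreement and diagnostic statistics against closed-form oracles.

test_that("pearson_ci matches the direct covariance formula", {
  x <- 1:10
  expect_equal(pearson_ci(x, 2 * x)$r, 1)
  expect_equal(pearson_ci(x, -x)$r, -1)
  set.seed(42)
  a <- rnorm(100)
  b <- 0.6 * a + rnorm(100, sd = 0.5)
  res <- pearson_ci(a, b)
  oracle <- sum((a - mean(a)) * (b - mean(b))) /
    sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2))
  expect_equal(res$r, oracle, tolerance = 1e-12)
  # Fisher z CI brackets the estimate and matches the textbook interval
  z <- atanh(oracle); se <- 1 / sqrt(100 - 3)
  expect_equal(res$ci, tanh(z + c(-1, 1) * qnorm(0.975) * se),
               tolerance = 1e-12)
  expect_true(res$ci[1] < res$r && res$r < res$ci[2])
  expect_error(pearson_ci(rep(1, 10), 1:10), "constant")
})

test_that("ICC(2,1) equals a hand-rolled two-way ANOVA decomposition", {
  subj <- c(9, 6, 8, 7, 10, 6, 5, 8, 4, 7)
  x <- subj + c(0.1, -0.2, 0.3, 0, -0.1, 0.2, -0.3, 0.1, 0, -0.2)
  y <- subj + 0.5 + c(-0.1, 0.1, 0, 0.2, -0.2, 0, 0.1, -0.1, 0.2, 0)
  res <- icc(x, y)
  # independent oracle: explicit ANOVA sums of squares
  n <- 10; k <- 2
  dat <- cbind(x, y)
  grand <- mean(dat)
  msr <- k * sum((rowMeans(dat) - grand)^2) / (n - 1)
  msc <- n * sum((colMeans(dat) - grand)^2) / (k - 1)
  mse <- (sum((dat - grand)^2) - k * sum((rowMeans(dat) - grand)^2) -
            n * sum((colMeans(dat) - grand)^2)) / ((n - 1) * (k - 1))
  oracle <- (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
  expect_equal(res$icc, oracle, tolerance = 1e-9)
  expect_true(res$ci[1] <= res$icc && res$icc <= res$ci[2])
})

test_that("ICC penalizes fixed bias; perfect agreement gives 1", {
  subj <- c(12, 15, 19, 23, 27, 31, 35, 40)
  expect_equal(icc(subj, subj)$icc, 1)
  biased <- icc(subj, subj + 4)
  r <- pearson_ci(subj, subj + 4)$r
  expect_lt(biased$icc, r)
  expect_lte(biased$icc, abs(r) + 1e-9)
  expect_error(icc(rep(3, 8), rep(3, 8) + 0.1), "between-subject")
})

test_that("bland_altman matches direct formulas", {
  x <- c(1, 2, 3, 4)
  expect_equal(bland_altman(x, x),
               list(mean_diff = 0, sd_diff = 0, loa_low = 0, loa_high = 0,
                    n = 4))
  ba <- bland_altman(x + 2, x)
  expect_equal(ba$mean_diff, 2)
  expect_equal(ba$sd_diff, 0)
  set.seed(8)
  a <- rnorm(50, 30, 5)
  b <- a + rnorm(50, 1, 0.8)
  res <- bland_altman(a, b)
  d <- a - b
  expect_equal(res$mean_diff, mean(d), tolerance = 1e-12)
  expect_equal(res$sd_diff, sd(d), tolerance = 1e-12)
  expect_equal(res$loa_high - res$loa_low, 2 * 1.96 * sd(d),
               tolerance = 1e-9)
  expect_error(bland_altman(1, 1), ">= 2")
})

test_that("AUC equals the exhaustive positive-negative pair statistic", {
  sc <- c(0.9, 0.8, 0.7, 0.3, 0.2, 0.1)
  lb <- c(1, 1, 1, 0, 0, 0)
  expect_equal(roc_auc(sc, lb, ci_boot = 0)$auc, 1)
  expect_equal(roc_auc(rep(0.5, 8), rep(c(0, 1), 4), ci_boot = 0)$auc, 0.5)
  set.seed(3)
  scores <- round(rnorm(20), 1)           # rounding forces ties
  labels <- rbinom(20, 1, 0.5)
  if (length(unique(labels)) < 2) labels[1:2] <- c(0, 1)
  res <- roc_auc(scores, labels, ci_boot = 0)
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  pairs <- outer(pos, neg, function(p, q) (p > q) + 0.5 * (p == q))
  expect_equal(res$auc, mean(pairs), tolerance = 1e-12)
})

test_that("the ROC curve is monotone, anchored, and integrates to the AUC", {
  set.seed(9)
  scores <- rnorm(40)
  labels <- as.integer(scores + rnorm(40) > 0)
  if (length(unique(labels)) < 2) labels[1:2] <- c(0, 1)
  res <- roc_auc(scores, labels, ci_boot = 0)
  cv <- res$curve
  expect_equal(c(cv$fpr[1], cv$tpr[1]), c(0, 0))
  expect_equal(c(cv$fpr[nrow(cv)], cv$tpr[nrow(cv)]), c(1, 1))
  expect_true(all(diff(cv$fpr) >= 0) && all(diff(cv$tpr) >= 0))
  trap <- sum(diff(cv$fpr) * (head(cv$tpr, -1) + tail(cv$tpr, -1)) / 2)
  expect_equal(res$auc, trap, tolerance = 1e-9)
})

test_that("AUC is invariant under strictly monotone score transforms", {
  set.seed(13)
  scores <- rnorm(30)
  labels <- as.integer(scores + rnorm(30, sd = 0.7) > 0)
  if (length(unique(labels)) < 2) labels[1:2] <- c(0, 1)
  base <- roc_auc(scores, labels, ci_boot = 0)$auc
  expect_equal(roc_auc(exp(scores), labels, ci_boot = 0)$auc, base)
  expect_equal(roc_auc(scores^3 + 5 * scores, labels, ci_boot = 0)$auc, base)
})

test_that("bootstrap CI is seeded and reproducible", {
  set.seed(21)
  scores <- rnorm(30)
  labels <- as.integer(scores > 0.2)
  if (length(unique(labels)) < 2) labels[1:2] <- c(0, 1)
  a <- roc_auc(scores, labels, ci_boot = 300, seed = 99)
  b <- roc_auc(scores, labels, ci_boot = 300, seed = 99)
  expect_identical(a$ci, b$ci)
  expect_true(a$ci[1] <= a$auc + 1e-9 && a$auc <= a$ci[2] + 1e-9)
  expect_error(roc_auc(scores, rep(1, 30)), "both classes")
})

test_that("youden_optimal matches an exhaustive threshold sweep", {
  sc <- c(0.9, 0.8, 0.7, 0.3, 0.2, 0.1)
  lb <- c(1, 1, 1, 0, 0, 0)
  op <- youden_optimal(roc_auc(sc, lb, ci_boot = 0))
  expect_equal(op$sensitivity, 1)
  expect_equal(op$specificity, 1)
  op0 <- youden_optimal(roc_auc(rep(1, 6), lb, ci_boot = 0))
  expect_equal(op0$youden, 0)
  set.seed(17)
  scores <- rnorm(20)
  labels <- as.integer(scores + rnorm(20) > 0)
  if (length(unique(labels)) < 2) labels[1:2] <- c(0, 1)
  op2 <- youden_optimal(roc_auc(scores, labels, ci_boot = 0))
  ths <- c(Inf, sort(unique(scores), decreasing = TRUE), -Inf)
  js <- vapply(ths, function(t) {
    sens <- mean(scores[labels == 1] > t)
    spec <- mean(scores[labels == 0] <= t)
    sens + spec - 1
  }, 0)
  expect_equal(op2$youden, max(js), tolerance = 1e-12)
})
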