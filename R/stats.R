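#' Pearson correlation with Fisher-z confidence interval
#'
#' Sample correlation with a `level` CI from the Fisher z transform,
#' standard error `1 / sqrt(n - 3)`.
#'
#' @param x,y paired numeric vectors, n >= 4, both non-constant.
#' @param level confidence level. Default 0.95.
#' @return `list(r, ci = c(lower, upper), n)`.
#' @export
pearson_ci <- function(x, y, level = 0.95) {
  n <- length(x)
  if (n != length(y) || n < 4)
    stop("need >= 4 complete pairs", call. = FALSE)
  if (stats::sd(x) < 1e-12 || stats::sd(y) < 1e-12)
    stop("correlation undefined for constant input", call. = FALSE)
  r <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  z <- atanh(min(max(r, -1 + 1e-15), 1 - 1e-15))
  se <- 1 / sqrt(n - 3)
  q <- stats::qnorm(1 - (1 - level) / 2)
  list(r = r, ci = tanh(c(z - q * se, z + q * se)), n = n)
}

#' Intraclass correlation ICC(2,1) with confidence interval
#'
#' Two-way random effects, absolute agreement, single measurement — the form
#' matching a method-comparison design where both "raters" (e.g. a reference
#' and an automated method) measure every subject:
#' `(MSR - MSE) / (MSR + (k-1) MSE + (k/n)(MSC - MSE))`, mean squares from
#' the two-way ANOVA decomposition with k = 2 raters. The CI is the F-based
#' interval for ICC(2,1) (McGraw & Wong).
#'
#' @param x,y paired measurements of the same n >= 4 subjects by two
#'   methods.
#' @param level confidence level. Default 0.95.
#' @return `list(icc, ci = c(lower, upper), n, ms = list(msr, msc, mse))`.
#' @export
icc <- function(x, y, level = 0.95) {
  n <- length(x)
  if (n != length(y) || n < 4) stop("need >= 4 paired measurements",
                                    call. = FALSE)
  k <- 2
  dat <- cbind(x, y)
  row_m <- rowMeans(dat)
  col_m <- colMeans(dat)
  grand <- mean(dat)
  if (stats::var(row_m) < 1e-12)
    stop("zero between-subject variance; ICC undefined", call. = FALSE)
  ssr <- k * sum((row_m - grand)^2)
  ssc <- n * sum((col_m - grand)^2)
  sse <- sum((dat - outer(row_m, rep(1, k)) -
                outer(rep(1, n), col_m) + grand)^2)
  msr <- ssr / (n - 1)
  msc <- ssc / (k - 1)
  mse <- sse / ((n - 1) * (k - 1))
  est <- (msr - mse) / (msr + (k - 1) * mse + (k / n) * (msc - mse))

  # F-based CI for ICC(2,1), McGraw & Wong (1996)
  alpha <- 1 - level
  a <- (k * est) / (n * (1 - est))
  b <- 1 + (k * est * (n - 1)) / (n * (1 - est))
  v <- (a * msc + b * mse)^2 /
    ((a * msc)^2 / (k - 1) + (b * mse)^2 / ((n - 1) * (k - 1)))
  f1 <- stats::qf(1 - alpha / 2, n - 1, v)
  f2 <- stats::qf(1 - alpha / 2, v, n - 1)
  lower <- n * (msr - f1 * mse) /
    (f1 * (k * msc + (k * n - k - n) * mse) + n * msr)
  upper <- n * (f2 * msr - mse) /
    (k * msc + (k * n - k - n) * mse + n * f2 * msr)
  list(icc = est, ci = c(lower, upper), n = n,
       ms = list(msr = msr, msc = msc, mse = mse))
}

#' Bland-Altman analysis
#'
#' Differences `d = x - y`: mean, sample SD (n-1 denominator) and the 95%
#' limits of agreement `mean +- 1.96 SD`.
#'
#' @param x,y paired numeric vectors, n >= 2.
#' @return `list(mean_diff, sd_diff, loa_low, loa_high, n)`.
#' @export
bland_altman <- function(x, y) {
  n <- length(x)
  if (n != length(y) || n < 2) stop("need >= 2 pairs", call. = FALSE)
  d <- x - y
  m <- mean(d)
  s <- stats::sd(d)
  list(mean_diff = m, sd_diff = s,
       loa_low = m - 1.96 * s, loa_high = m + 1.96 * s, n = n)
}

#' ROC curve, AUC and bootstrap confidence interval
#'
#' AUC via the Mann-Whitney U statistic with midrank tie handling (equal to
#' the trapezoidal area under the threshold-sweep curve); the curve sweeps
#' the unique score values as thresholds with the convention
#' "positive if score > threshold". The CI is a seeded nonparametric
#' percentile bootstrap over cases.
#'
#' @param scores numeric predictions (higher = more positive).
#' @param labels binary 0/1 (or logical) truth; both classes required.
#' @param ci_boot bootstrap replicates. Default 2000; 0 skips the CI.
#' @param seed integer RNG seed for the bootstrap.
#' @param level confidence level. Default 0.95.
#' @return a `roc_result`: `auc`, `ci`, `curve` (data.frame `threshold`,
#'   `fpr`, `tpr` from (0,0) to (1,1)), `n_pos`, `n_neg`.
#' @export
roc_auc <- function(scores, labels, ci_boot = 2000, seed = 1L,
                    level = 0.95) {
  labels <- as.integer(as.logical(labels))
  if (length(scores) != length(labels))
    stop("'scores' and 'labels' lengths differ", call. = FALSE)
  npos <- sum(labels == 1)
  nneg <- sum(labels == 0)
  if (npos == 0 || nneg == 0)
    stop("both classes must be present for ROC analysis", call. = FALSE)

  auc_point <- auc_mw(scores, labels)
  thr <- sort(unique(scores), decreasing = TRUE)
  tpr <- vapply(thr, function(t) sum(scores > t & labels == 1) / npos, 0)
  fpr <- vapply(thr, function(t) sum(scores > t & labels == 0) / nneg, 0)
  curve <- data.frame(threshold = c(Inf, thr), fpr = c(0, fpr),
                      tpr = c(0, tpr))
  if (curve$fpr[nrow(curve)] != 1 || curve$tpr[nrow(curve)] != 1)
    curve <- rbind(curve, data.frame(threshold = -Inf, fpr = 1, tpr = 1))

  ci <- c(NA_real_, NA_real_)
  if (ci_boot > 0) {
    ci <- with_preserved_seed(seed, {
      n <- length(scores)
      reps <- vapply(seq_len(ci_boot), function(b) {
        ix <- sample.int(n, n, replace = TRUE)
        if (length(unique(labels[ix])) < 2) return(NA_real_)
        auc_mw(scores[ix], labels[ix])
      }, 0)
      alpha <- 1 - level
      as.numeric(stats::quantile(reps, c(alpha / 2, 1 - alpha / 2),
                                 na.rm = TRUE, type = 7))
    })
  }
  structure(list(auc = auc_point, ci = ci, curve = curve,
                 n_pos = npos, n_neg = nneg),
            class = "roc_result")
}

# Mann-Whitney AUC with midranks
auc_mw <- function(scores, labels) {
  r <- rank(scores, ties.method = "average")
  npos <- sum(labels == 1)
  nneg <- sum(labels == 0)
  (sum(r[labels == 1]) - npos * (npos + 1) / 2) / (npos * nneg)
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("<roc_result> AUC = %.3f [%.3f, %.3f], %d pos / %d neg\n",
              x$auc, x$ci[1], x$ci[2], x$n_pos, x$n_neg))
  invisible(x)
}

#' Youden-optimal operating point of an ROC curve
#'
#' The threshold maximizing `sensitivity + specificity - 1`; ties broken by
#' higher sensitivity, then lower threshold.
#'
#' @param roc a [roc_auc()] result.
#' @return `list(threshold, sensitivity, specificity, youden)`.
#' @export
youden_optimal <- function(roc) {
  cv <- roc$curve
  sens <- cv$tpr
  spec <- 1 - cv$fpr
  j <- sens + spec - 1
  ord <- order(-j, -sens, cv$threshold)
  best <- ord[1]
  list(threshold = cv$threshold[best], sensitivity = sens[best],
       specificity = spec[best], youden = j[best])
}
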