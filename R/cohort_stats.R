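
#' Spearman rank correlation with confidence interval
#'
#' Spearman's r computed as the Pearson correlation of mid-ranks (average
#' ranks for ties) after pairwise deletion of missing values. The p-value uses
#' the t approximation `t = r * sqrt((n - 2) / (1 - r^2))` on `n - 2` degrees
#' of freedom; the 95% interval uses the Fisher z transform with the
#' rank-correlation standard error `1.03 / sqrt(n - 3)`.
#'
#' @param x,y paired numeric vectors.
#' @param conf_level confidence level (default 0.95).
#' @return object of class `correlation_result`: `r`, `p_value`, `ci_low`,
#'   `ci_high`, `n`.
#' @export
spearman_cor <- function(x, y, conf_level = 0.95) {
  if (length(x) != length(y))
    stop_fovea("x and y must be paired (lengths %d, %d)", length(x), length(y))
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 4) stop_fovea("need at least 4 complete pairs (have %d)", n)
  rx <- rank(x); ry <- rank(y)
  if (var(rx) == 0 || var(ry) == 0)
    stop_fovea("constant input: rank variance is zero")
  r <- cor(rx, ry)
  if (abs(r) >= 1 - 1e-12) {
    p <- 0
  } else {
    tstat <- r * sqrt((n - 2) / (1 - r^2))
    p <- 2 * pt(-abs(tstat), n - 2)
  }
  se <- 1.03 / sqrt(n - 3)
  zq <- qnorm(1 - (1 - conf_level) / 2)
  z <- atanh(min(max(r, -1 + 1e-15), 1 - 1e-15))
  structure(list(r = r, p_value = p, ci_low = tanh(z - zq * se),
                 ci_high = tanh(z + zq * se), n = n),
            class = "correlation_result")
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf("Spearman r = %.3f (95%% CI %.3f to %.3f), p = %.4g, n = %d\n",
              x$r, x$ci_low, x$ci_high, x$p_value, x$n))
  invisible(x)
}

#' Paired t test
#'
#' @param x,y paired numeric vectors.
#' @return list `t`, `df`, `p_value`, `mean_diff`, `n`.
#' @export
paired_t <- function(x, y) {
  if (length(x) != length(y))
    stop_fovea("x and y must be paired (lengths %d, %d)", length(x), length(y))
  ok <- is.finite(x) & is.finite(y)
  d <- x[ok] - y[ok]
  n <- length(d)
  if (n < 2) stop_fovea("need at least 2 complete pairs")
  s <- sd(d)
  m <- mean(d)
  if (s == 0) {
    if (m == 0) return(list(t = 0, df = n - 1, p_value = 1, mean_diff = 0,
                            n = n))
    warn_fovea("zero variance of differences with nonzero mean: p = 0")
    return(list(t = sign(m) * Inf, df = n - 1, p_value = 0, mean_diff = m,
                n = n))
  }
  tstat <- m / (s / sqrt(n))
  list(t = tstat, df = n - 1, p_value = 2 * pt(-abs(tstat), n - 1),
       mean_diff = m, n = n)
}

#' Intergrader intraclass correlation (two-way random effects, single rater)
#'
#' ICC(2,1) from the two-way ANOVA decomposition, absolute agreement by
#' default so that a systematic offset between graders penalizes agreement;
#' a consistency variant is selectable. The confidence interval is the
#' standard F-based interval. The paired t test between graders is reported
#' alongside.
#'
#' @param grader1,grader2 paired numeric vectors (one value per subject).
#' @param model `"agreement"` (ICC(2,1), default) or `"consistency"`.
#' @param conf_level confidence level (default 0.95).
#' @return object of class `agreement_result`: `icc`, `ci_low`, `ci_high`,
#'   `model`, `n`, and the paired test fields `t_stat`, `df`, `p_value`.
#' @export
icc_two_grader <- function(grader1, grader2,
                           model = c("agreement", "consistency"),
                           conf_level = 0.95) {
  model <- match.arg(model)
  if (length(grader1) != length(grader2))
    stop_fovea("grader vectors must be paired")
  ok <- is.finite(grader1) & is.finite(grader2)
  g1 <- grader1[ok]; g2 <- grader2[ok]
  n <- length(g1)
  if (n < 5) stop_fovea("need at least 5 complete pairs (have %d)", n)
  k <- 2
  x <- cbind(g1, g2)
  grand <- mean(x)
  if (var(as.vector(x)) == 0) stop_fovea("zero total variance")
  rowm <- rowMeans(x)
  colm <- colMeans(x)
  msr <- k * sum((rowm - grand)^2) / (n - 1)
  msc <- n * sum((colm - grand)^2) / (k - 1)
  res <- x - outer(rowm, rep(1, k)) - outer(rep(1, n), colm) + grand
  mse <- sum(res^2) / ((n - 1) * (k - 1))
  alpha <- 1 - conf_level
  if (model == "agreement") {
    icc <- (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
    a <- k * icc / (n * (1 - icc))
    b <- 1 + k * icc * (n - 1) / (n * (1 - icc))
    v <- (a * msc + b * mse)^2 /
      ((a * msc)^2 / (k - 1) + (b * mse)^2 / ((n - 1) * (k - 1)))
    fl <- qf(1 - alpha / 2, n - 1, v)
    fu <- qf(1 - alpha / 2, v, n - 1)
    lo <- n * (msr - fl * mse) /
      (fl * (k * msc + (k * n - k - n) * mse) + n * msr)
    hi <- n * (fu * msr - mse) /
      (k * msc + (k * n - k - n) * mse + n * fu * msr)
  } else {
    icc <- (msr - mse) / (msr + (k - 1) * mse)
    f <- msr / mse
    fl <- f / qf(1 - alpha / 2, n - 1, (n - 1) * (k - 1))
    fu <- f * qf(1 - alpha / 2, (n - 1) * (k - 1), n - 1)
    lo <- (fl - 1) / (fl + k - 1)
    hi <- (fu - 1) / (fu + k - 1)
  }
  tt <- paired_t(g1, g2)
  structure(list(icc = icc, ci_low = lo, ci_high = hi, model = model, n = n,
                 t_stat = tt$t, df = tt$df, p_value = tt$p_value),
            class = "agreement_result")
}

#' @export
print.agreement_result <- function(x, ...) {
  cat(sprintf(
    "ICC(%s) = %.3f (95%% CI %.3f to %.3f), n = %d; paired t = %.3f, df = %d, p = %.4g\n",
    x$model, x$icc, x$ci_low, x$ci_high, x$n, x$t_stat, x$df, x$p_value))
  invisible(x)
}

#' Per-metric cohort summary
#'
#' Minimum, maximum, median and interquartile range (Q3 - Q1,
#' linear-interpolation quantiles) for each metric column, with counts of
#' available and missing values.
#'
#' @param table data frame of per-participant metrics.
#' @param metrics character vector of column names; defaults to all numeric
#'   columns.
#' @return data frame with one row per metric.
#' @export
cohort_summary <- function(table, metrics = NULL) {
  if (is.null(metrics))
    metrics <- names(table)[vapply(table, is.numeric, TRUE)]
  rows <- lapply(metrics, function(m) {
    v <- table[[m]]
    v <- v[is.finite(v)]
    if (length(v) == 0) {
      warn_fovea("metric '%s' has no values; omitted", m)
      return(NULL)
    }
    q <- quantile(v, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
    data.frame(metric = m, n = length(v),
               n_missing = sum(!is.finite(table[[m]])),
               min = min(v), max = max(v), median = q[2], iqr = q[3] - q[1])
  })
  do.call(rbind, rows)
}

#' Spearman correlations over a list of metric pairs
#'
#' Applies [spearman_cor()] per pair with pairwise deletion. By default no
#' multiple-testing correction is applied (raw p-values are reported and a
#' note emitted); Holm adjustment can be requested.
#'
#' @param table data frame of per-participant metrics.
#' @param pairs two-column character matrix or list of length-2 character
#'   vectors naming metric columns.
#' @param adjust `"none"` (default) or `"holm"`.
#' @return data frame: `var1`, `var2`, `r`, `p_value`, `ci_low`, `ci_high`,
#'   `n` (and `p_adj` when adjusted).
#' @export
correlation_matrix <- function(table, pairs, adjust = c("none", "holm")) {
  adjust <- match.arg(adjust)
  if (is.list(pairs)) pairs <- do.call(rbind, pairs)
  pairs <- as.matrix(pairs)
  missing_cols <- setdiff(unique(as.vector(pairs)), names(table))
  if (length(missing_cols) > 0)
    stop_fovea("unknown column(s): %s", paste(missing_cols, collapse = ", "))
  res <- lapply(seq_len(nrow(pairs)), function(i) {
    s <- spearman_cor(table[[pairs[i, 1]]], table[[pairs[i, 2]]])
    data.frame(var1 = pairs[i, 1], var2 = pairs[i, 2], r = s$r,
               p_value = s$p_value, ci_low = s$ci_low, ci_high = s$ci_high,
               n = s$n)
  })
  out <- do.call(rbind, res)
  if (adjust == "holm") {
    out$p_adj <- stats::p.adjust(out$p_value, method = "holm")
  } else {
    message("p-values are unadjusted for multiple testing")
  }
  out
}
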