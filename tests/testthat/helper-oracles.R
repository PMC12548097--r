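# Independent oracles used across the suite. These deliberately avoid the
# package's computational paths: plain loops and closed forms only.

# brute-force sliding-window density recount (cones/mm^2), O(N * G)
brute_density_map <- function(coords, roi_w, roi_h, window, step) {
  xc <- seq(window / 2, roi_w - window / 2, by = step)
  yc <- seq(window / 2, roi_h - window / 2, by = step)
  out <- matrix(0, length(yc), length(xc))
  for (i in seq_along(yc)) {
    for (j in seq_along(xc)) {
      n <- sum(coords[, 1] >= xc[j] - window / 2 &
               coords[, 1] <  xc[j] + window / 2 &
               coords[, 2] >= yc[i] - window / 2 &
               coords[, 2] <  yc[i] + window / 2)
      out[i, j] <- n / (window / 1000)^2
    }
  }
  out
}

# density-weighted centroid of the thresholded *analytic* density surface,
# evaluated on a fine grid (oracle for the CDC)
brute_cdc_analytic <- function(dens_fun, roi_w, roi_h, fraction,
                               step = 0.5) {
  xs <- seq(0, roi_w, by = step)
  ys <- seq(0, roi_h, by = step)
  d <- outer(ys, xs, function(y, x) dens_fun(x, y))
  thr <- fraction * max(d)
  keep <- d >= thr
  idx <- which(keep, arr.ind = TRUE)
  w <- d[keep]
  c(x = sum(xs[idx[, 2]] * w) / sum(w), y = sum(ys[idx[, 1]] * w) / sum(w))
}

# ICC(2,1) via stats::aov mean squares (independent of the package's ANOVA)
icc21_aov <- function(g1, g2) {
  n <- length(g1)
  df <- data.frame(y = c(g1, g2),
                   subj = factor(rep(seq_len(n), 2)),
                   rater = factor(rep(1:2, each = n)))
  ms <- summary(stats::aov(y ~ subj + rater, data = df))[[1]][, "Mean Sq"]
  msr <- ms[1]; msc <- ms[2]; mse <- ms[3]
  k <- 2
  (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
}

# mean of a function over [-h, h] by fine trapezoidal quadrature
fine_interval_mean <- function(f, h, n = 20001) {
  x <- seq(-h, h, length.out = n)
  y <- f(x)
  sum((y[-1] + y[-n]) / 2 * diff(x)) / (2 * h)
}
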