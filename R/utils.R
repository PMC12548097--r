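
# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_fovea <- function(...) stop(sprintf(...), call. = FALSE)
warn_fovea <- function(...) warning(sprintf(...), call. = FALSE)

check_positive <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0)
    stop_fovea("'%s' must be a single positive finite number (got %s)",
               name, paste(format(x), collapse = ", "))
  invisible(x)
}

#' Bilinear interpolation of a gridded image in physical coordinates
#'
#' Grid values are stored as a matrix with rows = y (increasing downward) and
#' columns = x; the top-left pixel center is the physical origin (0, 0) and
#' pixel centers sit at integer multiples of the per-axis scales.
#'
#' @param grid numeric matrix.
#' @param x_um,y_um query positions (micrometres), vectorised.
#' @param x_scale,y_scale micrometres per pixel along columns / rows.
#' @return interpolated values; `NA` outside the grid's convex hull of pixel
#'   centers.
#' @keywords internal
#' @noRd
interp_grid <- function(grid, x_um, y_um, x_scale, y_scale) {
  nr <- nrow(grid); nc <- ncol(grid)
  n <- max(length(x_um), length(y_um))
  x <- rep_len(x_um, n) / x_scale
  y <- rep_len(y_um, n) / y_scale
  out <- rep(NA_real_, n)
  ok <- x >= 0 & x <= nc - 1 & y >= 0 & y <= nr - 1
  if (!any(ok)) return(out)
  x <- x[ok]; y <- y[ok]
  ix <- if (nc >= 2) pmax(pmin(floor(x), nc - 2), 0) else rep(0, length(x))
  iy <- if (nr >= 2) pmax(pmin(floor(y), nr - 2), 0) else rep(0, length(y))
  fx <- x - ix; fy <- y - iy
  i00 <- iy + 1 + ix * nr
  dx <- if (nc >= 2) nr else 0
  dy <- if (nr >= 2) 1 else 0
  v <- (1 - fx) * ((1 - fy) * grid[i00] + fy * grid[i00 + dy]) +
    fx * ((1 - fy) * grid[i00 + dx] + fy * grid[i00 + dx + dy])
  out[ok] <- v
  out
}

# moving-average smoothing with edge truncation (window = 2*halfwidth + 1).
# Sums are accumulated from shifted copies (not a long cumsum) so constant
# stretches stay exactly constant.
moving_average <- function(x, halfwidth) {
  if (halfwidth <= 0) return(x)
  n <- length(x)
  acc <- numeric(n)
  cnt <- numeric(n)
  for (off in -halfwidth:halfwidth) {
    src <- seq_len(n) + off
    ok <- src >= 1 & src <= n
    acc[ok] <- acc[ok] + x[src[ok]]
    cnt[ok] <- cnt[ok] + 1
  }
  acc / cnt
}

# local maxima of a vector (>= both neighbours, > at least one); returns indices
local_maxima <- function(x) {
  n <- length(x)
  if (n < 3) return(integer(0))
  i <- 2:(n - 1)
  i[x[i] >= x[i - 1] & x[i] >= x[i + 1] & (x[i] > x[i - 1] | x[i] > x[i + 1])]
}

# topographic prominence of the peak at index k: height above the higher of
# the two valley minima reached before a strictly higher point (or the end)
peak_prominence <- function(x, k) {
  n <- length(x)
  left <- x[k]
  i <- k - 1
  while (i >= 1 && x[i] <= x[k]) { left <- min(left, x[i]); i <- i - 1 }
  if (i < 1) left <- min(x[1:k])
  right <- x[k]
  i <- k + 1
  while (i <= n && x[i] <= x[k]) { right <- min(right, x[i]); i <- i + 1 }
  if (i > n) right <- min(x[k:n])
  x[k] - max(left, right)
}

# quadratic (parabolic) refinement of an extremum at integer index k given
# values v = x[k + (-1, 0, 1)]; returns list(offset in [-0.5, 0.5], value)
quadratic_refine <- function(vm1, v0, vp1) {
  denom <- vm1 - 2 * v0 + vp1
  if (!is.finite(denom) || abs(denom) < .Machine$double.eps * max(1, abs(v0)))
    return(list(offset = 0, value = v0))
  off <- 0.5 * (vm1 - vp1) / denom
  off <- max(-0.5, min(0.5, off))
  val <- v0 - 0.25 * (vm1 - vp1) * off
  # plateau edges make the parabola overshoot; keep within the sample range
  val <- max(min(val, max(vm1, v0, vp1)), min(vm1, v0, vp1))
  list(offset = off, value = val)
}

# nearest correlation matrix by eigenvalue clipping + unit-diagonal rescale
nearest_psd_correlation <- function(m, eps = 1e-8) {
  e <- eigen((m + t(m)) / 2, symmetric = TRUE)
  vals <- pmax(e$values, eps)
  r <- e$vectors %*% diag(vals, length(vals)) %*% t(e$vectors)
  d <- sqrt(diag(r))
  r <- r / tcrossprod(d)
  diag(r) <- 1
  (r + t(r)) / 2
}

# connected components of a logical matrix (wrapper around the C++ kernel)
label_components <- function(mask, connectivity = 4L) {
  stopifnot(is.logical(mask), is.matrix(mask), connectivity %in% c(4L, 8L))
  cpp_label_components(mask, as.integer(connectivity))
}

# 2-D box (moving-average) smoothing with edge truncation; hx/hy are
# half-widths in columns/rows. Cumsum-based, O(n).
box_smooth <- function(m, hx, hy) {
  if (hx <= 0 && hy <= 0) return(m)
  nr <- nrow(m); nc <- ncol(m)
  S <- matrix(0, nr + 1L, nc + 1L)
  S[-1, -1] <- m
  for (j in 2:(nc + 1L)) S[, j] <- S[, j] + S[, j - 1L]
  for (i in 2:(nr + 1L)) S[i, ] <- S[i, ] + S[i - 1L, ]
  r1 <- pmax(seq_len(nr) - hy, 1L); r2 <- pmin(seq_len(nr) + hy, nr)
  c1 <- pmax(seq_len(nc) - hx, 1L); c2 <- pmin(seq_len(nc) + hx, nc)
  sums <- S[r2 + 1L, c2 + 1L, drop = FALSE] - S[r1, c2 + 1L, drop = FALSE] -
    S[r2 + 1L, c1, drop = FALSE] + S[r1, c1, drop = FALSE]
  sums / outer(r2 - r1 + 1L, c2 - c1 + 1L)
}

# trapezoidal mean of y over x (assumes x sorted, length >= 2)
trapz_mean <- function(x, y) {
  pracma::trapz(x, y) / (x[length(x)] - x[1])
}
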