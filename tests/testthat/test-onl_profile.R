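make_scan <- function(seed = 1, nr = 80, nc = 120) {
  set.seed(seed)
  # smooth-ish structure so cross-correlation has a clear optimum
  base <- outer(sin(seq(0, 6, length.out = nr)),
                cos(seq(0, 8, length.out = nc))) +
    matrix(rnorm(nr * nc, 0, 0.3), nr, nc)
  bscan_image(base, 1.95, 6)
}

test_that("directional-OCT alignment recovers known integer shifts", {
  ref <- make_scan(3)
  # identity: zero shift, NCC = 1
  res <- align_doct(list(ref, ref))
  expect_equal(res$shifts[2, ], c(rows = 0, cols = 0))
  expect_equal(res$ncc[2], 1, tolerance = 1e-12)
  # constructed shift (+3 rows, -2 cols) is undone
  shifted <- bscan_image(foveamorph:::shift_image(ref$pixels, c(3, -2)),
                         1.95, 6)
  res <- align_doct(list(ref, shifted))
  expect_equal(res$shifts[2, ], c(rows = -3, cols = 2))
  expect_gt(res$ncc[2], 0.95)
  # noisy triad (SNR ~ 10): shifts still recovered exactly
  set.seed(9)
  noisy <- lapply(list(c(2, 5), c(-4, -1)), function(sh) {
    px <- foveamorph:::shift_image(ref$pixels, sh) +
      matrix(rnorm(length(ref$pixels), 0, 0.1), nrow(ref$pixels))
    bscan_image(px, 1.95, 6)
  })
  res <- align_doct(c(list(ref), noisy))
  expect_equal(res$shifts[2, ], c(rows = -2, cols = -5))
  expect_equal(res$shifts[3, ], c(rows = 4, cols = 1))
})

test_that("max-intensity merge is idempotent, commutative and monotone", {
  a <- make_scan(11); b <- make_scan(12); c3 <- make_scan(13)
  expect_equal(merge_doct(list(a, a))$pixels, a$pixels)
  m1 <- merge_doct(list(a, b, c3))
  m2 <- merge_doct(list(c3, a, b))
  expect_equal(m1$pixels, m2$pixels)
  # elementwise oracle
  expect_equal(m1$pixels, pmax(a$pixels, b$pixels, c3$pixels))
  # monotone: adding a scan cannot decrease any pixel
  expect_true(all(m1$pixels >= merge_doct(list(a, b))$pixels))
  expect_error(merge_doct(list(a)), "at least 2")
})

test_that("boundary interpolation is exact at knots and refuses extrapolation", {
  pts <- cbind(c(0, 10), c(10, 20))
  expect_equal(interpolate_boundary(pts, 5), 15)
  expect_equal(interpolate_boundary(pts, c(0, 10)), c(10, 20))
  expect_error(interpolate_boundary(pts, 11), "extrapolation")
  # linear function through 30 knots is reproduced exactly everywhere
  x <- seq(0, 290, by = 10)
  pts <- cbind(x, 50 + 0.1 * x)
  q <- seq(0, 290, by = 0.7)
  expect_equal(interpolate_boundary(pts, q), 50 + 0.1 * q, tolerance = 1e-12)
})

test_that("ONL thickness is the HFL/ONL-to-ELM gap and shift-invariant", {
  x <- seq(0, 1000, length.out = 30)
  seg <- boundary_segmentation(
    list(HFL_ONL = cbind(x, 100), ELM = cbind(x, 130)),
    axial_um_per_px = 2, lateral_um_per_px = 1)
  prof <- onl_thickness_profile(seg)
  expect_true(all(abs(prof$thickness_um - 60) < 1e-9))
  # common axial translation of all boundaries leaves thickness unchanged
  seg2 <- boundary_segmentation(
    list(HFL_ONL = cbind(x, 101), ELM = cbind(x, 131)),
    axial_um_per_px = 2, lateral_um_per_px = 1)
  expect_equal(onl_thickness_profile(seg2)$thickness_um, prof$thickness_um)
  # ordering violation is an error naming the position
  seg_bad <- list(HFL_ONL = cbind(x, 130), ELM = cbind(x, 100))
  expect_error(boundary_segmentation(seg_bad, 2, 1), "ordering")
})

test_that("noise-free synthetic segmentation recovers the analytic profile", {
  ss <- synth_segmentation()
  om <- onl_metrics(ss$seg)
  expect_lt(abs(om$max_onl_um - ss$truth$max_onl_um), 1)
  truth_central <- ss$truth$central_onl_fun(227)
  expect_lt(abs(om$central_onl_um - truth_central) / truth_central, 0.005)
  expect_equal(om$foveal_center_x_um, ss$truth$center_x_um, tolerance = 1e-6)
  # piecewise-linear reconstruction error stays below (h^2 / 8) * max|f''|
  prof <- onl_thickness_profile(ss$seg)
  xq <- prof$x_um - ss$truth$center_x_um
  h <- 6000 / 30
  fpp_max <- 40 / 600^2  # Gaussian bump: max |f''| = amplitude / sigma^2
  bound <- h^2 * fpp_max / 8
  expect_lt(max(abs(prof$thickness_um - ss$truth$onl_fun(xq))), bound + 1e-9)
})

test_that("foveal center localization handles symmetry, offsets and edges", {
  # pit centered on a knot: recovered exactly
  ss <- synth_segmentation(center_offset_um = 200)
  expect_equal(locate_foveal_center(ss$seg), 3200, tolerance = 1e-6)
  # monotone thickness in the window: edge warning
  x <- seq(0, 1000, length.out = 30)
  seg <- boundary_segmentation(
    list(ILM = cbind(x, 100 + 0.05 * x), RPE = cbind(x, 300)),
    axial_um_per_px = 2, lateral_um_per_px = 1)
  expect_warning(locate_foveal_center(seg, 400), "edge")
})

test_that("max search window finds a displaced peak; summaries need coverage", {
  # profile with its maximum 400 um from the center
  x <- seq(-1000, 1000, by = 5)
  th <- 80 + 30 * exp(-(x - 400)^2 / (2 * 150^2))
  prof <- list(x_um = x, thickness_um = th)
  s <- onl_summaries(prof, center_x_um = 0)
  expect_equal(s$max_onl_x_um, 400, tolerance = 5)
  # constant profile: max = central = the constant
  prof2 <- list(x_um = x, thickness_um = rep(100, length(x)))
  s2 <- onl_summaries(prof2, 0)
  expect_equal(s2$max_onl_um, 100)
  expect_equal(s2$central_onl_um, 100)
  # insufficient lateral coverage is an error
  expect_error(onl_summaries(prof, center_x_um = 800), "cover")
})

test_that("noisy segmentations keep max-ONL bias small and center on target", {
  set.seed(21)
  mx <- numeric(100)
  ctr <- numeric(50)
  for (i in 1:100) {
    s <- synth_segmentation(z_noise_px = 1)
    o <- onl_metrics(s$seg)
    mx[i] <- o$max_onl_um
    if (i <= 50) ctr[i] <- o$foveal_center_x_um
  }
  expect_lt(abs(mean(mx) - 100), 2)
  expect_gte(mean(abs(ctr - 3000) <= 20), 0.95)
})

test_that("grader averaging is the elementwise mean of paired values", {
  expect_equal(grader_average(100, 100), 100)
  expect_equal(grader_average(90, 110), 100)
  set.seed(2)
  a <- rnorm(20, 100, 10); b <- rnorm(20, 100, 10)
  loop <- vapply(seq_along(a), function(i) mean(c(a[i], b[i])), numeric(1))
  expect_equal(grader_average(a, b), loop)
  expect_error(grader_average(1:3, 1:2), "paired")
})
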