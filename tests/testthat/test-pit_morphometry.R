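test_that("pit center is found with sub-pixel refinement and tie rules", {
  tm <- synth_thickness_map(center_offset_um = c(40, -30))
  ctr <- find_pit_center(tm$map)
  expect_lt(abs(ctr["x"] - tm$truth$center_um["x"]),
            max(tm$map$x_um_per_px, tm$map$y_um_per_px))
  expect_lt(abs(ctr["y"] - tm$truth$center_um["y"]),
            max(tm$map$x_um_per_px, tm$map$y_um_per_px))
  # flat map: geometric center, with a warning
  flat <- thickness_map(matrix(250, 64, 64), 20, 20)
  expect_warning(ctr2 <- find_pit_center(flat, 300), "flat")
  # 64 pixels: the geometric center falls between two pixel centers; the tie
  # rule returns one of the two equidistant candidates
  expect_true(all(abs(ctr2 - 63 / 2 * 20) <= 10))
})

test_that("radial profiles respect isotropy in physical coordinates", {
  # isotropic physical surface sampled on an anisotropic grid
  tm <- synth_thickness_map(n_x = 512, n_y = 128)
  prof <- radial_profiles(tm$map, tm$truth$center_um, n_angles = 36,
                          max_radius_um = 2000)
  # every ray sees (nearly) the same radial function
  spread <- apply(prof$values, 2, function(v) diff(range(v, na.rm = TRUE)))
  expect_lt(max(spread, na.rm = TRUE), 1.5)
  # and matches the analytic profile up to bilinear error
  mid <- colMeans(prof$values, na.rm = TRUE)
  expect_lt(max(abs(mid - tm$truth$profile_fun(prof$radii_um))), 1.5)
  # constant map: every profile is the constant
  cm <- thickness_map(matrix(300, 50, 200), 10, 40)
  p2 <- radial_profiles(cm, c(x = 995, y = 245), n_angles = 12,
                        max_radius_um = 200)
  expect_true(all(abs(p2$values - 300) < 1e-9))
})

test_that("rim detection finds the first prominent maximum or falls back", {
  r <- seq(0, 2000, by = 10)
  # rises to a max at 1000 um then declines
  v <- 300 - 80 * exp(-(r / 500)^2) + 0 - 3e-5 * pmax(0, r - 700)^2
  k <- detect_rim(v, r)
  dense <- seq(0, 2000, by = 0.1)
  vd <- 300 - 80 * exp(-(dense / 500)^2) - 3e-5 * pmax(0, dense - 700)^2
  expect_lt(abs(k$rim_radius_um - dense[which.max(vd)]), 10)
  expect_false(k$fallback)
  # monotonically increasing profile: fallback to the outermost sample
  v2 <- 200 + 0.05 * r
  k2 <- detect_rim(v2, r)
  expect_true(k2$fallback)
  expect_equal(k2$rim_radius_um, 2000, tolerance = 10)
})

test_that("pit diameter averages opposed rim pairs; ellipse oracle agrees", {
  n <- 180
  th <- 2 * pi * (seq_len(n) - 1) / n
  # constant rim 950 um -> diameter 1.90 mm
  rims <- data.frame(angle = th, rim_radius_um = 950, rim_height_um = 330,
                     valid = TRUE)
  expect_equal(pit_diameter(rims)$diameter_mm, 1.90)
  # elliptical rim: radius function r(t) = a b / sqrt((b cos)^2 + (a sin)^2)
  a <- 800; b <- 1200
  re <- a * b / sqrt((b * cos(th))^2 + (a * sin(th))^2)
  rims$rim_radius_um <- re
  oracle <- mean(re[1:(n / 2)] + re[(n / 2 + 1):n]) / 1000
  expect_equal(pit_diameter(rims)$diameter_mm, oracle)
  # missing pairs are excluded and counted
  rims$valid[c(1, 92)] <- FALSE  # knocks out opposed pairs 1 and 2
  d <- pit_diameter(rims)
  expect_equal(d$n_excluded_pairs, 2)
})

test_that("cylindrical pit reproduces the closed-form volume", {
  # thickness H - d inside radius R, H outside; volume = pi R^2 d
  n <- 600; s <- 10
  xs <- (seq_len(n) - 1) * s
  ctr <- (n - 1) / 2 * s
  r <- sqrt(outer((xs - ctr)^2, (xs - ctr)^2, `+`))
  H <- 300; d <- 50; R <- 1000
  grid <- ifelse(r < R, H - d, H)
  suppressWarnings(pm <- pit_metrics(thickness_map(grid, s, s),
                                     radial_step_um = 10))
  expect_lt(abs(pm$volume_mm3 - pi * 1^2 * 0.05) / (pi * 0.05), 0.01)
  expect_equal(pm$diameter_mm, 2, tolerance = 0.06)
})

test_that("synthetic pits recover diameter and volume against quadrature", {
  models <- list(
    list(rim = 740, tc = 280, tr = 320),
    list(rim = 950, tc = 220, tr = 330),
    list(rim = 1320, tc = 230, tr = 340))
  for (m in models) {
    tm <- synth_thickness_map(t_center_um = m$tc, t_rim_um = m$tr,
                              rim_radius_um = m$rim)
    pm <- pit_metrics(tm$map)
    expect_lt(abs(pm$diameter_mm - tm$truth$diameter_mm), 2 * 10 / 1000)
    expect_lt(abs(pm$volume_mm3 - tm$truth$volume_mm3) / tm$truth$volume_mm3,
              0.02)
    expect_equal(pm$n_valid_angles, 180)
  }
})

test_that("pit metrics are stable under rotation and scale-equivariant", {
  tm <- synth_thickness_map(n_x = 256, n_y = 256)
  pm <- pit_metrics(tm$map)
  rot <- thickness_map(t(tm$map$grid[nrow(tm$map$grid):1, ]),
                       tm$map$y_um_per_px, tm$map$x_um_per_px)
  pm90 <- pit_metrics(rot)
  expect_lt(abs(pm90$diameter_mm - pm$diameter_mm) / pm$diameter_mm, 0.01)
  expect_lt(abs(pm90$volume_mm3 - pm$volume_mm3) / pm$volume_mm3, 0.01)
  # doubling both lateral scales: diameter x2, volume x4
  sc <- thickness_map(tm$map$grid, 2 * tm$map$x_um_per_px,
                      2 * tm$map$y_um_per_px)
  pms <- pit_metrics(sc, max_radius_um = 6000)
  expect_equal(pms$diameter_mm, 2 * pm$diameter_mm, tolerance = 0.02)
  expect_equal(pms$volume_mm3, 4 * pm$volume_mm3, tolerance = 0.03)
})

test_that("deepening a pit increases volume and depth, not diameter", {
  tm <- synth_thickness_map()
  pm <- pit_metrics(tm$map)
  g <- tm$map$grid
  xs <- (seq_len(ncol(g)) - 1) * tm$map$x_um_per_px
  ys <- (seq_len(nrow(g)) - 1) * tm$map$y_um_per_px
  r <- sqrt(outer((ys - tm$truth$center_um["y"])^2,
                  (xs - tm$truth$center_um["x"])^2, `+`))
  deeper <- thickness_map(pmax(g - 30 * exp(-(r / 400)^2), 1),
                          tm$map$x_um_per_px, tm$map$y_um_per_px)
  pm2 <- pit_metrics(deeper)
  expect_gt(pm2$volume_mm3, pm$volume_mm3)
  expect_gt(pm2$depth_um, pm$depth_um)
  expect_lt(abs(pm2$diameter_mm - pm$diameter_mm), 0.1)
})
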