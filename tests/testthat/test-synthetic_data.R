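test_that("generators are seed-deterministic", {
  a <- synth_mosaic(seed = 99)$mosaic$coords
  b <- synth_mosaic(seed = 99)$mosaic$coords
  expect_identical(a, b)
  expect_false(identical(a, synth_mosaic(seed = 100)$mosaic$coords))
  s1 <- synth_segmentation(z_noise_px = 1, seed = 5)$seg$boundaries
  s2 <- synth_segmentation(z_noise_px = 1, seed = 5)$seg$boundaries
  expect_identical(s1, s2)
  v1 <- synth_vessel_mask(seed = 6)$vm$mask
  v2 <- synth_vessel_mask(seed = 6)$vm$mask
  expect_identical(v1, v2)
  t1 <- synth_cohort(n = 20, seed = 7)$table
  t2 <- synth_cohort(n = 20, seed = 7)$table
  expect_identical(t1, t2)
})

test_that("uniform-density dart throwing realizes the requested density", {
  sm <- synth_mosaic(peak_density = 1e5, base_density = 99999,
                     sigma_um = 100, seed = 23)
  n <- nrow(sm$mosaic$coords)
  expect_lt(abs(n - 1e5 * 1e-6 * 300 * 300) / (1e5 * 1e-6 * 300 * 300), 0.05)
  # no pair closer than the inhibition radius at the local density
  d <- as.matrix(dist(sm$mosaic$coords))
  diag(d) <- Inf
  s_loc <- sqrt(2 / (sqrt(3) * 1e5 * 1e-6))
  expect_gt(min(d), 0.8 * s_loc * 0.9)  # sampler density is inflated ~11%
})

test_that("segmentation generator keeps boundary ordering under noise", {
  for (seed in 1:5) {
    ss <- synth_segmentation(z_noise_px = 2, seed = seed)
    b <- ss$seg$boundaries
    xq <- seq(max(vapply(b, function(m) m[1, 1], 0)),
              min(vapply(b, function(m) m[nrow(m), 1], 0)),
              length.out = 200)
    z <- vapply(names(b), function(nm) interpolate_boundary(b[[nm]], xq),
                numeric(200))
    ord <- z[, c("ILM", "OPL_HFL", "HFL_ONL", "ELM", "RPE")]
    expect_true(all(diff(t(ord)) >= -1e-9))
  }
})

test_that("thickness-map generator places the rim where requested", {
  for (rr in c(740, 950, 1320)) {
    tm <- synth_thickness_map(rim_radius_um = rr)
    expect_lt(abs(tm$truth$rim_radius_um - rr), 1)
    expect_equal(tm$truth$diameter_mm, 2 * tm$truth$rim_radius_um / 1000)
    # quadrature volume is positive and self-consistent with a coarse check
    rq <- seq(0, tm$truth$rim_radius_um, by = 5)
    coarse <- 2 * pi * sum(rq * pmax(0, tm$truth$rim_height_um -
                                          tm$truth$profile_fun(rq))) * 5 * 1e-9
    expect_lt(abs(coarse - tm$truth$volume_mm3) / tm$truth$volume_mm3, 0.01)
  }
})

test_that("noisy thickness maps give stable diameters", {
  set.seed(41)
  dia <- replicate(50, {
    tm <- synth_thickness_map(noise_sd_um = 2)
    pit_metrics(tm$map)$diameter_mm
  })
  expect_lt(sd(dia) / mean(dia), 0.03)
  # and noisy pit centers stay near the truth
  set.seed(42)
  err <- replicate(50, {
    tm <- synth_thickness_map(noise_sd_um = 2)
    ctr <- find_pit_center(tm$map)
    sqrt(sum((ctr - tm$truth$center_um)^2))
  })
  expect_gte(mean(err <= 50), 0.95)
})

test_that("vessel-mask generator conserves area and reports true fragments", {
  vs <- synth_vessel_mask(seed = 3)
  p <- label_picas(vs$vm)
  npx <- length(vs$vm$mask)
  expect_equal(sum(p$regions$area_mm2) + sum(vs$vm$mask) *
                 (vs$vm$um_per_px / 1000)^2,
               npx * (vs$vm$um_per_px / 1000)^2)
  # split proportions are approximately honoured
  vs2 <- synth_vessel_mask(split_proportions = c(0.6, 0.4), n_px = 300,
                           um_per_px = 10, seed = 4)
  props <- vs2$truth$fragment_areas_mm2 / sum(vs2$truth$fragment_areas_mm2)
  expect_lt(abs(props[1] - 0.6), 0.05)
})

test_that("copula conversion reproduces target rank correlations", {
  # brute-force check of rho_pearson = 2 sin(pi rho_s / 6) at one pair
  set.seed(51)
  rho_s <- -0.54
  rho_p <- 2 * sin(pi * rho_s / 6)
  z <- MASS::mvrnorm(1e6, c(0, 0), matrix(c(1, rho_p, rho_p, 1), 2))
  expect_lt(abs(cor(z[, 1], z[, 2], method = "spearman") - rho_s), 0.01)
})

test_that("cohort margins respect their bounds and medians", {
  ch <- synth_cohort(n = 500, seed = 52)
  mg <- default_cohort_margins()
  for (m in names(mg)) {
    v <- ch$table[[m]]
    expect_gte(min(v), mg[[m]]$min)
    expect_lte(max(v), mg[[m]]$max)
    expect_lt(abs(median(v) - mg[[m]]$median) /
                (mg[[m]]$max - mg[[m]]$min), 0.07)
  }
  # null targets stay null: independent metrics show small correlations
  R0 <- diag(8)
  dimnames(R0) <- dimnames(default_target_spearman())
  ch0 <- synth_cohort(n = 68, target_spearman = R0, seed = 53)
  r <- spearman_cor(ch0$table$pcd, ch0$table$faz_area_mm2)$r
  expect_lt(abs(r), 0.25)
})

test_that("synthetic cohorts recover a planted rank correlation", {
  ch <- synth_cohort(n = 68, seed = 54)
  r <- spearman_cor(ch$table$pcd, ch$table$pit_diameter_mm)$r
  band <- tanh(atanh(-0.54) + c(-1, 1) * qnorm(0.975) * 1.03 / sqrt(65))
  expect_gt(r, band[1])
  expect_lt(r, band[2])
})
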