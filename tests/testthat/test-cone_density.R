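test_that("cone mosaic validation catches bad inputs", {
  expect_error(cone_mosaic(matrix(numeric(0), 0, 2)), "empty")
  expect_error(cone_mosaic(cbind(c(10, 310), c(10, 10))), "outside")
  expect_error(cone_mosaic(cbind(c(10, 10), c(10, 10))), "duplicate")
  expect_warning(cone_mosaic(cbind(c(10, 10.1), c(10, 10))), "closer")
  m <- cone_mosaic(cbind(150, 150))
  expect_s3_class(m, "cone_mosaic")
})

test_that("density map counts a single cone and a regular lattice exactly", {
  # single cone at ROI center, 50 um window: 400 cones/mm^2 where counted
  m <- cone_mosaic(cbind(150, 150))
  dm <- density_map(m, 50, 10)
  expect_true(all(abs(dm$grid) < 1e-9 | abs(dm$grid - 400) < 1e-9))
  # node at (150,150) counts it; node at (100,100) does not
  expect_equal(dm$grid[13, 13], 400)   # node 13 sits at 25 + 12*10 = 145
  expect_equal(dm$grid[1, 1], 0)
  # regular lattice with pitch dividing the window side: uniform interior
  pitch <- 5
  xy <- expand.grid(x = seq(2.5, 297.5, pitch), y = seq(2.5, 297.5, pitch))
  lat <- cone_mosaic(as.matrix(xy), min_separation_um = 0)
  d_true <- 1 / (pitch / 1000)^2  # 40 000 cones/mm^2
  dml <- density_map(lat, 50, 10)
  expect_true(all(abs(dml$grid - d_true) < 1e-9))
})

test_that("summed-area-table counts equal a brute-force recount exactly", {
  set.seed(101)
  for (rep in 1:5) {
    n <- sample(50:200, 1)
    coords <- cbind(runif(n, 0, 100), runif(n, 0, 100))
    m <- cone_mosaic(coords, 100, 100, min_separation_um = 0)
    dm <- density_map(m, 40, 5)
    oracle <- brute_density_map(coords, 100, 100, 40, 5)
    expect_identical(dim(dm$grid), dim(oracle))
    expect_equal(dm$grid, oracle, tolerance = 0)
  }
})

test_that("window-count conservation holds for interior cones", {
  set.seed(7)
  coords <- cbind(runif(80, 30, 70), runif(80, 30, 70))
  m <- cone_mosaic(coords, 100, 100, min_separation_um = 0)
  w <- 40; step <- 5
  dm <- density_map(m, w, step)
  # every interior cone is counted by exactly (w/step)^2 windows on a grid
  # whose nodes cover it (half-open windows tile without overlap gaps)
  total_counts <- sum(dm$grid) * (w / 1000)^2
  xc <- seq(w / 2, 100 - w / 2, by = step)
  per_cone <- vapply(seq_len(nrow(coords)), function(i) {
    sum(xc > coords[i, 1] - w / 2 & xc <= coords[i, 1] + w / 2) *
      sum(xc > coords[i, 2] - w / 2 & xc <= coords[i, 2] + w / 2)
  }, numeric(1))
  expect_equal(total_counts, sum(per_cone))
})

test_that("density map is translation-equivariant", {
  set.seed(8)
  base <- cbind(runif(60, 10, 90), runif(60, 10, 90))
  m1 <- density_map(cone_mosaic(base, 120, 120, min_separation_um = 0), 40, 10)
  # shift cones and ROI by 20 um (= 2 grid steps): same values, shifted nodes
  m2 <- density_map(cone_mosaic(base + 20, 140, 140, min_separation_um = 0),
                    40, 10)
  expect_equal(m2$grid[3:11, 3:11], m1$grid, tolerance = 1e-12)
})

test_that("PCD tie-break picks the node nearest the ROI center", {
  m <- cone_mosaic(cbind(c(50, 250), c(150, 150)), 300, 300)
  dm <- density_map(m, 50, 25)
  pk <- peak_cone_density(dm)
  # both cones give equal window counts; winner must be nearer (150,150)
  alt <- sqrt(sum((c(250, 150) - c(150, 150))^2))
  expect_lte(sqrt(sum((pk$location_um - c(150, 150))^2)), alt)
})

test_that("CDC recovers a displaced synthetic density peak", {
  sm <- synth_mosaic(peak_density = 2e5, peak_offset_um = c(30, -20),
                     seed = 42)
  map <- density_map(sm$mosaic)
  met <- cdc(map)
  expect_lt(sqrt(sum((met$cdc_location_um - sm$truth$peak_um)^2)), 5)
  expect_lt(abs(met$pcd - sm$truth$peak_density) / sm$truth$peak_density, 0.05)
  # metric invariants
  expect_lte(met$cdc_density, met$pcd)
  expect_gte(met$cdc_density, met$fraction * met$pcd - 1e-9)
  # CDC agrees with the brute-force centroid of the thresholded analytic
  # density surface
  oracle <- brute_cdc_analytic(sm$truth$density_fun, 300, 300, 0.8)
  expect_lt(sqrt(sum((met$cdc_location_um - oracle)^2)), 5)
})

test_that("uniform map gives whole-grid contour and central CDC", {
  pitch <- 5
  xy <- expand.grid(x = seq(2.5, 297.5, pitch), y = seq(2.5, 297.5, pitch))
  m <- cone_mosaic(as.matrix(xy), min_separation_um = 0)
  dm <- density_map(m, 50, 10)
  met <- cdc(dm)
  expect_true(all(met$contour_mask))
  expect_equal(unname(met$cdc_location_um), c(150, 150), tolerance = 1e-9)
})

test_that("areal density uses the min CDC margin and the CDC row average", {
  pitch <- 5
  xy <- expand.grid(x = seq(2.5, 297.5, pitch), y = seq(2.5, 297.5, pitch))
  m <- cone_mosaic(as.matrix(xy), participant_id = "u1",
                   min_separation_um = 0)
  dm <- density_map(m, 50, 10)
  res <- areal_foveal_density(list(dm))
  # uniform mosaic: areal density = the uniform value; common width = ROI
  # minus the window margins
  expect_equal(res$areal$areal_density, 40000, tolerance = 1e-9)
  expect_equal(res$common_width_um, 300 - 50)
  # cohort: Gaussian mosaics, areal density matches the analytic row mean
  sms <- lapply(c(1.5e5, 2.5e5), function(p)
    synth_mosaic(peak_density = p, seed = round(p / 1000)))
  maps <- lapply(sms, function(s) density_map(s$mosaic))
  mets <- lapply(maps, cdc)
  ar <- areal_foveal_density(maps, mets)
  h <- ar$common_halfwidth_um
  for (i in 1:2) {
    f <- sms[[i]]$truth$density_fun
    cy <- mets[[i]]$cdc_location_um["y"]
    cx <- mets[[i]]$cdc_location_um["x"]
    truth <- fine_interval_mean(function(d) f(cx + d, cy), h)
    expect_lt(abs(ar$areal$areal_density[i] - truth) / truth, 0.03)
  }
})
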