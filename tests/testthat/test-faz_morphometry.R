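# a ring of vessel pixels enclosing a rectangular avascular region
ring_mask <- function(n = 60, r1 = c(20, 40), c1 = c(20, 40)) {
  m <- matrix(FALSE, n, n)
  m[r1[1]:r1[2], c1[1]:c1[2]] <- TRUE
  m[(r1[1] + 1):(r1[2] - 1), (c1[1] + 1):(c1[2] - 1)] <- FALSE
  m
}

test_that("angiogram averaging is the elementwise mean, order-invariant", {
  set.seed(3)
  imgs <- lapply(1:3, function(i) matrix(runif(100), 10, 10))
  avg <- average_angiograms(imgs)
  loop <- matrix(0, 10, 10)
  for (i in 1:10) for (j in 1:10)
    loop[i, j] <- mean(c(imgs[[1]][i, j], imgs[[2]][i, j], imgs[[3]][i, j]))
  expect_equal(avg, loop)
  expect_equal(avg, average_angiograms(rev(imgs)))
  expect_equal(average_angiograms(list(imgs[[1]], imgs[[1]])), imgs[[1]])
  expect_error(average_angiograms(imgs[1]), "2 to 10")
})

test_that("binarization recovers a bimodal mask and passes binary through", {
  vs <- synth_vessel_mask(seed = 31)
  img <- synth_angiogram(vs$vm, 200, 20)
  vm <- binarize_vessels(img, vs$vm$um_per_px)
  expect_identical(vm$mask, vs$vm$mask)
  # binary input passthrough
  vm2 <- binarize_vessels(vs$vm$mask * 1, vs$vm$um_per_px)
  expect_identical(vm2$mask, vs$vm$mask)
  # noisy angiogram (SNR ~ 5): >= 99% pixel agreement
  imgn <- synth_angiogram(vs$vm, 200, 20, noise_sd = 36, seed = 32)
  vmn <- binarize_vessels(imgn, vs$vm$um_per_px)
  expect_gte(mean(vmn$mask == vs$vm$mask), 0.99)
  expect_error(binarize_vessels(matrix(5, 4, 4), 10), "fixed")
})

test_that("PICA labelling counts enclosed regions and flags the border", {
  m <- ring_mask()
  vm <- vessel_mask(m, 10)
  p <- label_picas(vm)
  interior <- p$regions[!p$regions$touches_border, ]
  expect_equal(nrow(interior), 1)
  expect_equal(interior$area_mm2, 19 * 19 * (10 / 1000)^2)
  # two disjoint rings
  m2 <- ring_mask() | ring_mask(r1 = c(45, 58), c1 = c(10, 30))
  p2 <- label_picas(vessel_mask(m2, 10))
  int2 <- p2$regions[!p2$regions$touches_border, ]
  expect_equal(nrow(int2), 2)
  expect_setequal(int2$area_mm2, c(19 * 19, 12 * 19) * 1e-4)
  # area conservation: regions + vessels = image, exactly
  expect_equal(sum(p2$regions$area_mm2) + sum(m2) * 1e-4, 60 * 60 * 1e-4)
})

test_that("FAZ assignment applies the 0.3 ratio rule on central PICAs", {
  # three central rectangular PICAs with area ratios 1 : 0.4 : 0.05
  n <- 300
  m <- matrix(TRUE, n, n)
  m[121:160, 101:150] <- FALSE   # 40 x 50 = 2000 px = 0.20 mm^2 at 10 um/px
  m[121:160, 160:179] <- FALSE   # 40 x 20 =  800 px = 0.08 mm^2
  m[170:189, 140:144] <- FALSE   # 20 x 5  =  100 px = 0.01 mm^2
  vm <- vessel_mask(m, 10)
  res <- faz_area(vm)
  expect_equal(res$faz_area_mm2, 0.20)
  expect_equal(sort(unname(res$ratios)), c(0.05, 0.4, 1))
  expect_true(res$fragmented)
  expect_equal(res$n_central_picas, 3)
  # removing the middle region leaves a single-FAZ classification
  m2 <- m
  m2[121:160, 160:179] <- TRUE
  res2 <- faz_area(vessel_mask(m2, 10))
  expect_false(res2$fragmented)
  expect_equal(res2$faz_area_mm2, 0.20)
})

test_that("circular synthetic FAZ area matches the closed form", {
  vs <- synth_vessel_mask(faz_radius_um = 300, n_px = 300, um_per_px = 10,
                          seed = 7)
  res <- faz_area(vs$vm)
  expect_lt(abs(res$faz_area_mm2 - pi * 0.3^2) / (pi * 0.3^2), 0.02)
  expect_equal(res$faz_area_mm2, vs$truth$faz_area_mm2)
  expect_false(res$fragmented)
})

test_that("a traversing capillary fragments the FAZ per the ratio rule", {
  vs <- synth_vessel_mask(split_proportions = c(0.6, 0.4), n_px = 300,
                          um_per_px = 10, seed = 8)
  res <- faz_area(vs$vm)
  expect_true(res$fragmented)
  expect_equal(res$faz_area_mm2, vs$truth$fragment_areas_mm2[1])
  # smaller/larger fragment ratio is 0.4/0.6 > 0.3
  expect_gt(sort(res$ratios, decreasing = TRUE)[2], 0.3)
})

test_that("FAZ area is invariant to rotation/reflection, monotone in vessels", {
  vs <- synth_vessel_mask(seed = 13)
  a0 <- faz_area(vs$vm)$faz_area_mm2
  rot180 <- vessel_mask(vs$vm$mask[nrow(vs$vm$mask):1, ncol(vs$vm$mask):1],
                        vs$vm$um_per_px)
  expect_equal(faz_area(rot180)$faz_area_mm2, a0)
  refl <- vessel_mask(vs$vm$mask[, ncol(vs$vm$mask):1], vs$vm$um_per_px)
  expect_equal(faz_area(refl)$faz_area_mm2, a0)
  # dilating vessels by one pixel strictly shrinks the FAZ
  dil <- vessel_mask(foveamorph:::.dilate_plus(vs$vm$mask, 1),
                     vs$vm$um_per_px)
  expect_lt(faz_area(dil)$faz_area_mm2, a0)
})

test_that("classification is stable when no ratio is near the threshold", {
  # central areas far from the 0.3 boundary: perturbations don't flip the flag
  n <- 300
  m <- matrix(TRUE, n, n)
  m[121:160, 101:150] <- FALSE                 # ratio 1
  m[121:144, 160:179] <- FALSE                 # 480 px -> ratio 0.24 < 0.3
  base <- faz_area(vessel_mask(m, 10))
  expect_false(base$fragmented)
  # growing the second region to ratio 0.36 > 0.3 flips it
  m[121:156, 160:179] <- FALSE                 # 720 px -> ratio 0.36
  expect_true(faz_area(vessel_mask(m, 10))$fragmented)
})
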