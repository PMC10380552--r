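test_that("disk and square morphology match analytic geometry", {
  disk <- disk_mask(220, 220, 110, 110, 100)
  scan <- leaf_scan(array(0.5, c(220, 220, 3)), 300)
  m <- leaf_morphology(disk, scan)
  expect_gte(m$circularity, 0.95)
  expect_lte(m$circularity, 1.05)
  expect_equal(m$solidity, 1, tolerance = 0.01)
  expect_equal(m$leaf_area, sum(disk) * (25.4 / 300)^2 / 100)
  # axis-aligned square: boundary of straight chain codes; with the
  # bias-corrected perimeter (0.948/step) circularity is pi/4 / 0.948^2
  sq <- bar_mask(120, 120, 11, 90, 11, 90)
  ms <- leaf_morphology(sq, leaf_scan(array(0.5, c(120, 120, 3)), 300))
  a <- 80
  p_est <- 0.948 * 4 * (a - 1)
  expect_equal(ms$circularity, 4 * pi * a^2 / p_est^2, tolerance = 0.02)
  expect_equal(ms$solidity, 1, tolerance = 0.01)
})

test_that("color means are taken over leaf pixels only", {
  img <- array(1, c(20, 20, 3))
  mask <- bar_mask(20, 20, 5, 10, 5, 10)
  img[5:10, 5:10, 1] <- 0.2
  img[5:10, 5:10, 2] <- 0.6
  img[5:10, 5:10, 3] <- 0.4
  m <- leaf_morphology(mask, leaf_scan(img, 300))
  expect_equal(m$color_mean_r, 0.2)
  expect_equal(m$color_mean_g, 0.6)
  hsv <- grDevices::rgb2hsv(0.2, 0.6, 0.4, maxColorValue = 1)
  expect_equal(m$color_mean_hue, unname(hsv[1, 1]))
  expect_equal(m$color_mean_brightness, 0.6)
})

test_that("a straight bar yields its analytic vein length, diameter and class", {
  leaf <- matrix(TRUE, 40, 320)
  vein <- bar_mask(40, 320, 18, 23, 11, 310)  # 6 px wide, 300 px long
  v <- vein_traits(vein, leaf, dpi = 300)
  expect_equal(v$vein_total_length, 25.4, tolerance = 0.04 * 25.4)
  expect_equal(v$vein_mean_diameter, 0.508, tolerance = 0.06)
  # full length sits in the middle diameter class [0.25, 0.80)
  expect_equal(v$vein_length_class_b, v$vein_total_length)
  expect_equal(v$vein_length_class_a + v$vein_length_class_c, 0)
  expect_equal(v$vein_area, sum(vein) * (25.4 / 300)^2)
})

test_that("vein density spans its limits and classes partition the length", {
  leaf <- disk_mask(60, 60, 30, 30, 25)
  expect_equal(vein_traits(leaf, leaf, 300)$vein_density, 1)
  v0 <- vein_traits(matrix(FALSE, 60, 60), leaf, 300)
  expect_equal(v0$vein_density, 0)
  expect_equal(v0$vein_total_length, 0)
  smp <- fixture_leaf(101)
  v <- vein_traits(smp$vein_mask, smp$leaf_mask, 300)
  expect_equal(v$vein_length_class_a + v$vein_length_class_b +
                 v$vein_length_class_c,
               v$vein_total_length, tolerance = 0.01 * max(v$vein_total_length, 1))
})

test_that("doubling dpi halves every mm-valued vein trait", {
  smp <- fixture_leaf(101)
  v1 <- vein_traits(smp$vein_mask, smp$leaf_mask, 300)
  v2 <- vein_traits(smp$vein_mask, smp$leaf_mask, 600)
  expect_equal(v2$vein_total_length, v1$vein_total_length / 2)
  expect_equal(v2$vein_mean_diameter, v1$vein_mean_diameter / 2)
  expect_equal(v2$vein_area, v1$vein_area / 4)
  expect_equal(v2$vein_density, v1$vein_density)
})

test_that("petiole extraction takes the largest vein component outside the leaf", {
  smp <- fixture_leaf(101)
  full_veins <- smp$vein_mask | smp$petiole_mask
  pet <- petiole_extract(full_veins, smp$leaf_mask)
  expect_gte(jaccard(pet, smp$petiole_mask), 0.9)
  # veins wholly inside the leaf: no petiole
  expect_null(petiole_extract(smp$vein_mask & smp$leaf_mask, smp$leaf_mask))
  # two outside blobs: the larger one wins
  leaf <- bar_mask(40, 40, 1, 20, 1, 40)
  veins <- bar_mask(40, 40, 25, 30, 5, 8) | bar_mask(40, 40, 25, 36, 20, 24)
  pet2 <- petiole_extract(veins, leaf)
  expect_true(all(pet2[25:36, 20:24]))
  expect_false(any(pet2[25:30, 5:8]))
})

test_that("petiole measurements match analytic bar geometry", {
  bar <- bar_mask(40, 640, 15, 26, 21, 620)  # 12 px wide, 600 px long
  p <- petiole_measurements(bar, dpi = 300)
  expect_equal(p$petiole_length, 50.8, tolerance = 25.4 / 300)
  expect_equal(p$petiole_width, 1.016, tolerance = 0.1)
  expect_equal(p$petiole_area, sum(bar) * (25.4 / 300)^2)
  # 45-degree rotated bar: same rotated-rectangle length within 2%
  n <- 500
  diag_bar <- matrix(FALSE, 560, 560)
  for (k in 0:n) diag_bar[30 + k, 30 + k] <- TRUE
  for (d in 1:4) {
    diag_bar <- diag_bar | rbind(matrix(FALSE, 1, 560), diag_bar[-560, ])
  }
  pd <- petiole_measurements(diag_bar, dpi = 300)
  expect_equal(pd$petiole_length, sqrt(2) * n * 25.4 / 300, tolerance = 0.02 * 60)
})

test_that("petiole width uses the central fifth, not the flared ends", {
  # bar with thick ends and a thin uniform middle
  m <- bar_mask(60, 300, 28, 33, 11, 290)          # 6 px core
  m <- m | bar_mask(60, 300, 21, 40, 11, 50)       # 20 px left flare
  m <- m | bar_mask(60, 300, 21, 40, 251, 290)     # 20 px right flare
  p <- petiole_measurements(m, dpi = 300)
  expect_equal(p$petiole_width, 6 * 25.4 / 300, tolerance = 0.12)
})

test_that("full trait record combines all sections and flags missing petiole", {
  smp <- fixture_leaf(101)
  scan <- leaf_scan(smp$image, 300, "s101")
  tr <- extract_traits(scan, smp$leaf_mask, smp$vein_mask | smp$petiole_mask)
  expect_equal(tr$sample_id, "s101")
  expect_gt(tr$vein_density, 0)
  expect_gt(tr$petiole_length, 0)
  tr2 <- extract_traits(scan, smp$leaf_mask, smp$vein_mask & smp$leaf_mask)
  expect_true(is.na(tr2$petiole_length))
})
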