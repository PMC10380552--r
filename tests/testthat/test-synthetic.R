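test_that("generation is deterministic for identical parameters and seed", {
  p <- small_leaf_params(seed = 11)
  a <- generate_leaf(p)
  b <- generate_leaf(p)
  expect_identical(a$image, b$image)
  expect_identical(a$leaf_mask, b$leaf_mask)
  expect_identical(a$vein_mask, b$vein_mask)
  c <- generate_leaf(small_leaf_params(seed = 12))
  expect_false(identical(a$image, c$image))
})

test_that("background is near-white and the blade is not", {
  smp <- fixture_leaf(101)
  bg <- !(smp$leaf_mask | smp$petiole_mask)
  for (ch in 1:3) {
    expect_true(all(smp$image_clean[, , ch][bg] >= 0.9))
  }
  gray <- (smp$image_clean[, , 1] + smp$image_clean[, , 2] +
             smp$image_clean[, , 3]) / 3
  expect_true(all(gray[smp$leaf_mask] < 0.9))
})

test_that("a smooth margin yields near-disk circularity", {
  smp <- fixture_leaf(31, serration_amplitude = 0)
  morph <- leaf_morphology(smp$leaf_mask, leaf_scan(smp$image, 300))
  expect_gte(morph$circularity, 0.9)
})

test_that("branch depth zero gives a bare midrib with two skeleton endpoints", {
  smp <- fixture_leaf(31, vein_branch_depth = 0)
  vm <- smp$vein_mask & smp$leaf_mask
  expect_equal(connected_components(vm, 8)$count, 1)
  skel <- asNamespace("leaftrace")$cpp_skeletonize(vm)
  # endpoints = skeleton pixels with exactly one 8-neighbour
  pad <- matrix(FALSE, nrow(skel) + 2, ncol(skel) + 2)
  pad[2:(nrow(skel) + 1), 2:(ncol(skel) + 1)] <- skel
  nb <- matrix(0, nrow(skel), ncol(skel))
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    nb <- nb + pad[2:(nrow(skel) + 1) + dr, 2:(ncol(skel) + 1) + dc]
  }
  expect_equal(sum(skel & nb == 1), 2)
})

test_that("vein network is one connected component and veins sit inside the blade", {
  for (seed in c(101, 102, 103)) {
    smp <- fixture_leaf(seed)
    vm <- smp$vein_mask & smp$leaf_mask
    expect_equal(connected_components(vm, 8)$count, 1)
    expect_true(all(smp$vein_mask[!smp$leaf_mask] == FALSE))
  }
})

test_that("petiole touches but does not enter the blade", {
  smp <- fixture_leaf(101)
  expect_false(any(smp$petiole_mask & smp$leaf_mask))
  # 8-adjacent to the blade at the attachment
  H <- nrow(smp$leaf_mask)
  grown <- smp$leaf_mask
  grown[-1, ] <- grown[-1, ] | smp$leaf_mask[-H, ]
  expect_true(any(grown & smp$petiole_mask))
})

test_that("artifacts perturb the image only, never the masks", {
  p0 <- small_leaf_params(seed = 55)
  p1 <- small_leaf_params(seed = 55,
                          artifact_flags = c("fold", "white_stripe", "dust", "blur"))
  a <- generate_leaf(p0)
  b <- generate_leaf(p1)
  expect_identical(a$leaf_mask, b$leaf_mask)
  expect_identical(a$vein_mask, b$vein_mask)
  expect_identical(a$petiole_mask, b$petiole_mask)
  expect_false(identical(a$image, b$image))
  # the stripe artifact leaves a near-white vertical band
  stripe_cols <- which(apply(b$image[, , 1] >= 0.95, 2, all))
  expect_gt(length(stripe_cols), 0)
})

test_that("deeper branching never shortens the vein skeleton", {
  lens <- vapply(0:3, function(d) {
    smp <- fixture_leaf(77, vein_branch_depth = d)
    sum(asNamespace("leaftrace")$cpp_skeletonize(smp$vein_mask & smp$leaf_mask))
  }, numeric(1))
  expect_true(all(diff(lens) >= 0))
})

test_that("canvas too small for the lamina is a parameter error", {
  expect_error(small_leaf_params(seed = 1, canvas_size = c(120L, 100L)),
               class = "leaftrace_param_error")
})

test_that("population generator respects the clonal structure", {
  base <- small_leaf_params(seed = 1)
  expect_error(generate_population(5, base, 2, 2, 1, 1),
               class = "leaftrace_param_error")
  expect_error(generate_population(4, base, 2, 2, -1, 1),
               class = "leaftrace_param_error")
  # sigma_E = 0: clones of a genotype share the true trait value exactly
  pop <- generate_population(8, base, 4, 2, sigma_G = 0.2, sigma_E = 0,
                             seed = 3, render = FALSE)
  tv <- split(pop$assignments$trait_value, pop$assignments$genotype)
  for (v in tv) expect_equal(v[1], v[2])
  # sigma_G = 0: essentially no genetic variance in the trait
  pop0 <- generate_population(120, base, 60, 2, sigma_G = 0, sigma_E = 0.1,
                              seed = 4, render = FALSE)
  h <- heritability(pop0$assignments$trait_value, pop0$assignments$genotype)
  expect_lt(h$H2, 0.25)
})

test_that("rendered population carries genotype effects into the rasters", {
  base <- small_leaf_params(seed = 1)
  pop <- generate_population(2, base, 2, 1, sigma_G = 0.3, sigma_E = 0,
                             seed = 9, render = TRUE)
  expect_s3_class(pop$samples[[1]], "synthetic_sample")
  expect_equal(pop$samples[[1]]$params$genotype_effect,
               pop$assignments$genotype_effect[1])
})
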