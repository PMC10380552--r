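# Tile sampling, the growing loop with oracle classifiers, and
# connectivity-based threshold selection.

test_that("3x3 targets read the vein neighbourhood with rotation consistency", {
  lt <- asNamespace("leaftrace")
  vm <- bar_mask(20, 20, 8, 12, 3, 18)   # thick horizontal vein
  lab <- lt$neighborhood_labels(vm, 10, 10)
  expect_equal(lab, matrix(1, 3, 3))     # deep inside: all ones
  edge <- lt$neighborhood_labels(vm, 8, 10)
  expect_equal(edge[1, ], c(0, 0, 0))    # row above the vein
  # 90-degree rotation permutes tile and 3x3 target the same way, keeping
  # the centre pixel of the (even-sized) tile fixed
  tile <- array(runif(12 * 12 * 3), c(12, 12, 3))
  lab9 <- matrix(rbinom(9, 1, 0.5), 3, 3)
  ctr <- 7  # 12/2 + 1
  tr <- lt$rot90_tile_center(tile, 1)
  lr <- lt$rot90_mat(lab9, 1)
  expect_equal(tr[ctr, ctr, ], tile[ctr, ctr, ])
  # the pixel one step right of centre rotates to one step up of centre
  expect_equal(tr[ctr - 1, ctr, ], tile[ctr, ctr + 1, ])
  expect_equal(lr[1, 2], lab9[2, 3])
  # flips keep the centre fixed too and mirror the label columns
  tf <- lt$flip_tile_h_center(tile)
  expect_equal(tf[ctr, ctr, ], tile[ctr, ctr, ])
  expect_equal(tf[ctr, ctr - 1, ], tile[ctr, ctr + 1, ])
})

test_that("dataset size respects the positive/negative sampling bound", {
  smp <- fixture_leaf(101)
  V <- sum(smp$vein_mask & smp$leaf_mask)
  cfg <- scaled_grower_config(max_pos_per_image = Inf, neg_ratio = 10)
  # the interior holds fewer than 10x the vein pixels, so the builder warns
  # and samples every available background pixel
  expect_warning(
    ds <- build_grower_dataset(list(smp), cfg, augment = augment_none(),
                               seed = 1),
    "background")
  expect_lte(dim(ds$X)[4], 11 * V)
  expect_equal(nrow(ds$Y), 9)
  expect_true(all(ds$Y %in% c(0, 1)))
})

test_that("an all-background classifier visits only the seed neighbourhoods", {
  smp <- fixture_leaf(102)
  scan <- leaf_scan(smp$image, 300)
  null_oracle <- oracle_grower(matrix(FALSE, nrow(smp$leaf_mask),
                                      ncol(smp$leaf_mask)))
  acc <- grow_veins(null_oracle, scan, smp$leaf_mask, n_seeds = 50, seed = 3)
  expect_lte(sum(acc$visit_count > 0), 50 * 9)
  expect_equal(sum(accumulator_mean(acc)), 0)
})

test_that("an all-vein classifier floods every interior pixel exactly once", {
  leaf <- disk_mask(40, 40, 20, 20, 12)
  img <- array(0.5, c(40, 40, 3))
  all_oracle <- oracle_grower(matrix(TRUE, 40, 40))
  acc <- grow_veins(all_oracle, leaf_scan(img, 300), leaf, n_seeds = 5, seed = 1)
  # every leaf pixel was a centre exactly once: its own 3x3 contribution plus
  # one from each interior neighbour
  centers_contrib <- acc$visit_count
  expect_true(all(centers_contrib[leaf] >= 1))
  # total accumulated visits equal 9 per centre (minus out-of-bounds)
  expect_equal(sum(acc$visit_count), sum(leaf) * 9)
})

test_that("growing is deterministic given the seed", {
  smp <- fixture_leaf(102)
  scan <- leaf_scan(smp$image, 300)
  oracle <- oracle_grower(smp$vein_mask & smp$leaf_mask)
  a1 <- grow_veins(oracle, scan, smp$leaf_mask, n_seeds = 100, seed = 5)
  a2 <- grow_veins(oracle, scan, smp$leaf_mask, n_seeds = 100, seed = 5)
  expect_identical(a1$prob_sum, a2$prob_sum)
  expect_identical(a1$visit_count, a2$visit_count)
})

test_that("centres never leave the leaf mask (dilated-by-one containment)", {
  smp <- fixture_leaf(102)
  scan <- leaf_scan(smp$image, 300)
  all_oracle <- oracle_grower(matrix(TRUE, nrow(smp$leaf_mask),
                                     ncol(smp$leaf_mask)))
  acc <- grow_veins(all_oracle, scan, smp$leaf_mask, n_seeds = 50, seed = 2)
  dil <- EBImage::dilate(EBImage::Image(smp$leaf_mask * 1),
                         EBImage::makeBrush(3, "box"))
  expect_true(all(acc$visit_count[as.matrix(dil) == 0] == 0))
})

test_that("threshold selection minimises component count with ties to smaller", {
  # constant accumulator 0.6 on a block: both 0.5 and 0.7 give one component,
  # tie resolved towards 0.5
  acc <- prob_accumulator(c(10, 10))
  acc$prob_sum[3:7, 3:7] <- 0.6
  acc$visit_count[3:7, 3:7] <- 1
  sel <- select_threshold(acc, grid = c(0.5, 0.7))
  expect_equal(sel$theta, 0.5)
  # above the constant value the mask would be empty: infinite count
  sel_hi <- select_threshold(acc, grid = c(0.5, 0.65))
  expect_equal(sel_hi$theta, 0.5)
  expect_equal(sel_hi$counts$n_components[2], Inf)
  expect_error(select_threshold(prob_accumulator(c(5, 5))), "empty")
})

test_that("faint bridges between bright branches favour a lower threshold", {
  acc <- prob_accumulator(c(30, 30))
  acc$visit_count[, ] <- 1
  # two bright bars connected by a faint bridge
  acc$prob_sum[5, 5:25] <- 0.95
  acc$prob_sum[25, 5:25] <- 0.95
  acc$prob_sum[5:25, 15] <- 0.55
  sel <- select_threshold(acc, grid = seq(0.1, 0.9, by = 0.1))
  expect_lte(sel$theta, 0.5)
  n_at_09 <- connected_components(accumulator_mean(acc) >= 0.9, 8)$count
  expect_lt(connected_components(sel$mask, 8)$count, n_at_09)
  # component counts across the grid match a brute-force recount
  meanp <- accumulator_mean(acc)
  for (i in seq_len(nrow(sel$counts))) {
    th <- sel$counts$theta[i]
    m <- (acc$visit_count > 0) & (meanp >= th)
    expected <- if (!any(m)) Inf else flood_count(m, 8)
    expect_equal(sel$counts$n_components[i], expected)
  }
})

test_that("oracle growing plus threshold selection recovers the vein mask", {
  smp <- fixture_leaf(103)
  scan <- leaf_scan(smp$image, 300)
  truth <- smp$vein_mask & smp$leaf_mask
  oracle <- oracle_grower(truth)
  acc <- grow_veins(oracle, scan, smp$leaf_mask, n_seeds = 300, seed = 7)
  sel <- select_threshold(acc)
  expect_gte(jaccard(sel$mask, truth), 0.99)
  expect_lte(connected_components(sel$mask, 8)$count,
             connected_components(truth, 8)$count + 1)
})
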