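# Training-target construction and the iterative tracing loop. The heavier
# learned-model checks live in test-acceptance.R; here the loop is validated
# with a plug-in oracle that reads the ground-truth contour.

test_that("trace targets sample the contour evenly from centre outwards", {
  # straight horizontal boundary: a wide thin bar
  mask <- bar_mask(64, 400, 30, 34, 9, 392)
  img <- array(0.5, c(64, 400, 3))
  ct <- mask_to_contour(mask)
  # pick a start on the top edge, far from corners, oriented along +col
  pts <- ct$points
  idx_top <- which(pts[, 1] == 30 & pts[, 2] > 100 & pts[, 2] < 300)
  start <- idx_top[1]
  dir <- if (pts[((start) %% nrow(pts)) + 1, 2] > pts[start, 2]) 1L else -1L
  N <- 16; S <- 64
  tg <- make_trace_target(img, ct, start, dir, N, S, overlay_len = 32)
  # spacing (S/2)/N = 2 px along a straight edge: displacements (0, 2k),
  # with the final sample clamped at the tile-exit point (|dc| <= S/2 - 1)
  expect_equal(tg$displacements[1, ], rep(0, N))
  expect_equal(tg$displacements[2, 1:(N - 1)], 2 * seq_len(N - 1),
               tolerance = 1e-8)
  expect_lte(tg$displacements[2, N], S / 2 - 1)
  # direction -1 equals direction +1 of the reversed contour
  rev_ct <- leaf_contour(pts[rev(seq_len(nrow(pts))), ])
  start_rev <- which(rev_ct$points[, 1] == pts[start, 1] &
                       rev_ct$points[, 2] == pts[start, 2])[1]
  tg_rev <- make_trace_target(img, rev_ct, start_rev, -dir, N, S,
                              overlay_len = 32)
  expect_equal(tg$displacements, tg_rev$displacements, tolerance = 1e-8)
  # 4th channel marks the path behind the start, opposite the trace direction
  expect_gt(sum(tg$tile[, , 4]), 0)
  expect_error(make_trace_target(img, leaf_contour(pts[1:8, ]), 1, 1,
                                 N = 16, tile_size = S), "shorter")
})

test_that("trace targets land on the contour of a synthetic leaf", {
  smp <- fixture_leaf(101)
  ct <- mask_to_contour(smp$leaf_mask)
  cset <- paste(ct$points[, 1], ct$points[, 2])
  for (start in c(10, 200, 400)) {
    tg <- make_trace_target(smp$image, ct, start, 1L, N = 32, tile_size = 64,
                            overlay_len = 64)
    pts <- cbind(round(ct$points[start, 1] + tg$displacements[1, ]),
                 round(ct$points[start, 2] + tg$displacements[2, ]))
    hits <- paste(pts[, 1], pts[, 2]) %in% cset
    expect_gte(mean(hits), 0.9)  # rounding can push a point one pixel off
  }
})

test_that("spatial augmentation transforms displacements consistently", {
  disp <- rbind(c(1, 2, 3), c(4, 5, 6))
  rot180 <- asNamespace("leaftrace")$rotate_displacements(disp, pi)
  expect_equal(rot180, -disp, tolerance = 1e-12)
  rot90 <- asNamespace("leaftrace")$rotate_displacements(disp, pi / 2)
  expect_equal(rot90[1, ], -disp[2, ], tolerance = 1e-12)
  expect_equal(rot90[2, ], disp[1, ], tolerance = 1e-12)
})

test_that("dataset counting follows the contour subsampling", {
  smp <- fixture_leaf(101)
  ct <- mask_to_contour(smp$leaf_mask)
  P <- nrow(ct$points)
  cfg <- scaled_tracer_config()
  ds <- build_tracer_dataset(list(smp, fixture_leaf(102)), cfg,
                             augment = augment_none(), stride = 7L, seed = 1)
  P2 <- nrow(mask_to_contour(fixture_leaf(102)$leaf_mask)$points)
  expect_equal(dim(ds$X)[4], length(seq(1, P, by = 7)) + length(seq(1, P2, by = 7)))
  expect_equal(dim(ds$X)[1:3], c(64, 64, 4))
  expect_equal(nrow(ds$Y), 2 * cfg$N)
})

test_that("oracle tracing reproduces the ground-truth mask", {
  smp <- fixture_leaf(103)
  scan <- leaf_scan(smp$image, 300)
  oracle <- oracle_tracer(smp$leaf_mask)
  res <- trace_leaf(oracle, scan, scaled_tracer_config())
  expect_gte(jaccard(res$mask, smp$leaf_mask), 0.99)
  # the filled mask is one component without holes
  expect_equal(connected_components(res$mask, 8)$count, 1)
  holes <- connected_components(!res$mask, 4)$count
  expect_equal(holes, 1)  # only the surrounding background
  # closure cannot fire before the guard window has accumulated
  expect_gt(res$iterations,
            scaled_tracer_config()$burn_in + 2)
})

test_that("oracle tracing is equivariant under quarter-turn rotation", {
  smp <- fixture_leaf(104)
  rot_mask <- t(smp$leaf_mask)[rev(seq_len(ncol(smp$leaf_mask))), ]
  rot_img <- array(0, c(dim(rot_mask), 3))
  for (ch in 1:3) {
    rot_img[, , ch] <- t(smp$image[, , ch])[rev(seq_len(ncol(smp$image[, , ch]))), ]
  }
  res1 <- trace_leaf(oracle_tracer(smp$leaf_mask), leaf_scan(smp$image, 300),
                     scaled_tracer_config())
  res2 <- trace_leaf(oracle_tracer(rot_mask), leaf_scan(rot_img, 300),
                     scaled_tracer_config())
  back <- t(res2$mask[rev(seq_len(nrow(res2$mask))), ])
  expect_gte(jaccard(back, res1$mask), 0.97)
})
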