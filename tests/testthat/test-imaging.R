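test_that("pixel-to-physical conversion follows the DPI definition", {
  expect_equal(px_to_physical(300, 300), 25.4)
  expect_equal(px_to_physical(0, 300), 0)
  expect_equal(px_to_physical(6, 300), 0.508)
  # linearity
  a <- runif(10, 0, 500); b <- runif(10, 0, 500)
  expect_equal(px_to_physical(a + b, 300),
               px_to_physical(a, 300) + px_to_physical(b, 300))
  expect_error(px_to_physical(-1, 300), "negative")
  expect_error(px_to_physical(10, 0), "dpi")
})

test_that("rough foreground finds the leaf and rejects empty scans", {
  smp <- fixture_leaf(101)
  scan <- leaf_scan(smp$image, 300)
  mask <- rough_foreground(scan)
  expect_gte(jaccard(mask, smp$leaf_mask | smp$petiole_mask), 0.9)
  white <- leaf_scan(array(0.97, c(40, 40, 3)), 300)
  expect_error(rough_foreground(white), class = "leaftrace_no_object")
})

test_that("rough foreground keeps only the largest component (dust rejected)", {
  img <- array(0.96, c(60, 60, 3))
  img[20:40, 20:40, ] <- 0.3    # object
  img[5:6, 5:6, ] <- 0.1        # dust speck
  mask <- rough_foreground(leaf_scan(img, 300))
  expect_true(all(mask[20:40, 20:40]))
  expect_false(any(mask[5:6, 5:6]))
})

test_that("tile extraction centres, pads and round-trips correctly", {
  img <- array(runif(50 * 40 * 3), c(50, 40, 3))
  tl <- extract_tile(img, c(25, 20), 16)
  expect_equal(dim(tl$pixels), c(16, 16, 3))
  expect_false(any(tl$pad_mask))
  # centre pixel lands at index size/2 + 1
  expect_equal(tl$pixels[9, 9, ], img[25, 20, ])
  # re-embedding non-padded pixels reproduces the source exactly
  expect_equal(tl$pixels[, , 1], img[17:32, 12:27, 1])
  # corner tile: top-left quadrant is padding
  tc <- extract_tile(img, c(1, 1), 16)
  expect_true(all(tc$pad_mask[1:8, 1:8]))
  expect_false(any(tc$pad_mask[9:16, 9:16]))
  expect_true(all(tc$pixels[1:8, 1:8, ] == 1))
  # constant image gives a constant (non-padded) tile
  cimg <- array(0.5, c(50, 40, 3))
  ct <- extract_tile(cimg, c(25, 20), 16)
  expect_true(all(ct$pixels == 0.5))
  expect_error(extract_tile(img, c(0, 5), 16), "outside")
})

test_that("connected components match enumeration and an independent oracle", {
  expect_equal(connected_components(matrix(FALSE, 5, 5))$count, 0)
  diagm <- matrix(c(TRUE, FALSE, FALSE, TRUE), 2, 2)
  expect_equal(connected_components(diagm, 8)$count, 1)
  expect_equal(connected_components(diagm, 4)$count, 2)
  plus <- matrix(FALSE, 5, 5); plus[3, 2:4] <- TRUE; plus[2:4, 3] <- TRUE
  expect_equal(connected_components(plus, 4)$count, 1)
  expect_equal(connected_components(plus, 8)$count, 1)
  withr::with_seed(42, {
    for (i in 1:8) {
      m <- matrix(runif(16 * 16) < 0.4, 16, 16)
      for (conn in c(4, 8)) {
        expect_equal(connected_components(m, conn)$count, flood_count(m, conn))
      }
    }
  })
})

test_that("boundary walk is ordered, complete and round-trips through fill", {
  one <- matrix(FALSE, 5, 5); one[3, 3] <- TRUE
  expect_equal(nrow(mask_to_contour(one)$points), 1)
  sq <- bar_mask(5, 5, 2, 4, 2, 4)
  ct <- mask_to_contour(sq)
  expect_equal(nrow(ct$points), 8)
  # consecutive boundary pixels are 8-adjacent
  d <- abs(diff(ct$points))
  expect_true(all(pmax(d[, 1], d[, 2]) == 1))
  # fill(trace(mask)) recovers the mask for simply-connected blobs
  withr::with_seed(7, {
    for (i in 1:5) {
      m <- disk_mask(30, 30, 15, 15, runif(1, 4, 10))
      ct2 <- mask_to_contour(m)
      expect_identical(fill_contour(ct2, c(30, 30)), m)
    }
  })
  two <- matrix(FALSE, 5, 5); two[1, 1] <- TRUE; two[5, 5] <- TRUE
  expect_error(mask_to_contour(two), "components")
})

test_that("contour filling includes boundary and is orientation-invariant", {
  sq <- bar_mask(7, 7, 2, 4, 2, 4)
  ct <- mask_to_contour(sq)
  filled <- fill_contour(ct, c(7, 7))
  expect_equal(sum(filled), 9)
  one <- leaf_contour(matrix(c(3, 3), 1, 2))
  expect_equal(sum(fill_contour(one, c(5, 5))), 1)
  rev_ct <- leaf_contour(ct$points[rev(seq_len(nrow(ct$points))), ])
  expect_identical(fill_contour(rev_ct, c(7, 7)), filled)
  open_ct <- leaf_contour(ct$points, closed = FALSE)
  expect_error(fill_contour(open_ct, c(7, 7)), "closed")
})
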