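test_that("jaccard index matches set arithmetic and is symmetric", {
  a <- bar_mask(6, 6, 1, 2, 1, 2)   # 2x2 block
  b <- bar_mask(6, 6, 2, 3, 1, 2)   # overlapping 2x2 block (2 px overlap)
  expect_equal(jaccard(a, a), 1)
  expect_equal(jaccard(a, b), 2 / 6)
  expect_equal(jaccard(a, b), jaccard(b, a))
  disj <- bar_mask(6, 6, 5, 6, 5, 6)
  expect_equal(jaccard(a, disj), 0)
  empty <- matrix(FALSE, 6, 6)
  expect_equal(jaccard(empty, empty), 1)
  expect_error(jaccard(a, matrix(FALSE, 5, 5)), "shape")
})

test_that("recall counts detected foreground", {
  truth <- bar_mask(6, 6, 2, 3, 2, 5)
  expect_equal(recall(truth | bar_mask(6, 6, 5, 6, 5, 6), truth), 1)
  expect_equal(recall(matrix(FALSE, 6, 6), truth), 0)
  half <- truth; half[, 4:5] <- FALSE
  expect_equal(recall(half, truth), 0.5)
  expect_error(recall(truth, matrix(FALSE, 6, 6)), "empty")
})

test_that("component-count comparison groups models by Tukey HSD", {
  same <- component_count_comparison(list(a = c(3, 4, 3, 4), b = c(4, 3, 4, 3)))
  expect_equal(same$summary$group[1], same$summary$group[2])
  diff_counts <- list(low = c(1, 1, 1, 2), high = c(100, 101, 100, 99))
  cmp <- component_count_comparison(diff_counts)
  expect_false(cmp$summary$group[cmp$summary$model == "low"] ==
                 cmp$summary$group[cmp$summary$model == "high"])
  # grouping structure is invariant under relabelling
  relab <- component_count_comparison(list(zz = diff_counts$low,
                                           aa = diff_counts$high))
  expect_equal(length(unique(cmp$summary$group)),
               length(unique(relab$summary$group)))
  expect_error(component_count_comparison(list(a = 1:3)), "2 models")
  expect_error(component_count_comparison(list(a = 1, b = 2)), "observations")
})

test_that("linear validation recovers exact and near-exact relations", {
  x <- c(1, 2, 3, 4, 5)
  v <- linear_validation(x, x)
  expect_equal(v$r_squared, 1)
  expect_equal(v$slope, 1)
  expect_equal(v$intercept, 0)
  # constant reference: no variance explained
  vc <- linear_validation(x, rep(2, 5))
  expect_equal(vc$r_squared, 0)
  # tiny noise: slope near 2, R^2 near 1
  withr::with_seed(1, {
    y <- 2 * x + rnorm(5, 0, 1e-6)
    vn <- linear_validation(x, y)
    expect_equal(vn$slope, 2, tolerance = 1e-4)
    expect_gt(vn$r_squared, 0.999)
  })
  expect_error(linear_validation(rep(1, 5), x), "variance")
  expect_error(linear_validation(1:2, 1:2), "3")
  td <- tidy(v); gl <- glance(v)
  expect_equal(td$estimate[td$term == "slope"], 1)
  expect_equal(gl$r_squared, 1)
})

test_that("heritability handles the degenerate variance structures", {
  g <- rep(1:4, each = 3)
  # no within-genotype variance, clear between: H2 = 1
  v1 <- rep(c(1, 5, 9, 13), each = 3)
  expect_equal(heritability(v1, g)$H2, 1)
  # identical genotype means, positive within variance: H2 truncated to 0
  v0 <- rep(c(-1, 0, 1), times = 4)
  expect_equal(heritability(v0, g)$H2, 0)
  expect_error(heritability(1:4, 1:4), "singleton")
  expect_error(heritability(1:4, rep(1, 4)), "2 genotypes")
})

test_that("heritability is scale invariant and the MAD filter drops outliers", {
  withr::with_seed(10, {
    g <- rep(1:50, each = 2)
    v <- rnorm(50, 0, 1)[g] + rnorm(100, 0, 1)
    h1 <- heritability(v, g)
    h2 <- heritability(v * 7.3, g)
    expect_equal(h1$H2, h2$H2, tolerance = 1e-10)
    # a gross outlier distorts the estimate unless filtered
    v_out <- v; v_out[1] <- 1e3
    h_filt <- heritability(v_out, g, mad_filter = 6)
    expect_equal(h_filt$n_used, 99)
    expect_equal(h_filt$H2, heritability(v[-1], g[-1])$H2, tolerance = 1e-10)
  })
})

test_that("heritability recovers 0.5 when variances are equal", {
  withr::with_seed(11, {
    h2s <- vapply(1:40, function(i) {
      g <- rep(1:200, each = 2)
      v <- rnorm(200, 0, 1)[g] + rnorm(400, 0, 1)
      heritability(v, g)$H2
    }, numeric(1))
    expect_equal(mean(h2s), 0.5, tolerance = 0.05)
  })
})

test_that("tidy and glance summarise heritability estimates", {
  g <- rep(1:4, each = 3)
  v <- rep(c(1, 5, 9, 13), each = 3) + rep(c(-0.1, 0, 0.1), 4)
  h <- heritability(v, g)
  td <- tidy(h)
  expect_equal(td$variance[td$component == "environmental"], h$sigma2_E)
  expect_equal(sum(td$proportion), 1)
  expect_equal(glance(h)$n_genotypes, 4)
})
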