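test_that("mean distance to centroid matches hand-worked configurations", {
  expect_equal(mean_distance_to_centroid(cbind(c(1, -1, 0, 0), c(0, 0, 1, -1))), 1)
  expect_equal(mean_distance_to_centroid(matrix(2, 4L, 2L)), 0)
  expect_equal(mean_distance_to_centroid(cbind(c(0, 2), c(0, 0))), 1)
  expect_error(mean_distance_to_centroid(matrix(numeric(0), 0L, 2L)), "empty")
})

test_that("identical groups give observed 0 and p = 1 in both tests", {
  set.seed(3)
  a <- cbind(rnorm(10), rnorm(10))
  for (f in list(dispersion_difference_test, centroid_distance_test)) {
    r <- f(a, a, n_perm = 99L, seed = 1L)
    expect_equal(r$observed, 0)
    expect_equal(r$p_value, 1)
  }
})

test_that("p-values respect the add-one rule bounds", {
  set.seed(4)
  a <- cbind(rnorm(12), rnorm(12))
  b <- cbind(rnorm(12, 5), rnorm(12))
  r <- centroid_distance_test(a, b, n_perm = 99L, seed = 2L)
  expect_gte(r$p_value, 1 / 100)  # minimum achievable at n_perm = 99
  expect_lte(r$p_value, 1)
  expect_equal(r$p_value, 0.01)   # a 5-sd shift is never matched by the null
  r2 <- dispersion_difference_test(a, b * 4, n_perm = 99L, seed = 2L)
  expect_gte(r2$p_value, 0.01)
  expect_error(centroid_distance_test(a, b, n_perm = 50L), "n_perm")
  expect_error(centroid_distance_test(a[1:2, ], b), "n >= 3")
})

test_that("tests are deterministic under a seed and leave the RNG untouched", {
  set.seed(10)
  a <- cbind(rnorm(9), rnorm(9)); b <- cbind(rnorm(11, 0.5), rnorm(11))
  set.seed(77)
  before <- .Random.seed
  r1 <- dispersion_difference_test(a, b, n_perm = 199L, seed = 42L)
  expect_identical(.Random.seed, before)
  r2 <- dispersion_difference_test(a, b, n_perm = 199L, seed = 42L)
  expect_identical(r1$p_value, r2$p_value)
  expect_identical(r1$null_quantiles, r2$null_quantiles)
  r3 <- dispersion_difference_test(a, b, n_perm = 199L, seed = 43L)
  expect_false(identical(r3$null_quantiles, r1$null_quantiles))
})

test_that("tests are invariant to group swap, row order and translation", {
  set.seed(20)
  a <- cbind(rnorm(9), rnorm(9)); b <- cbind(rnorm(13, 1), rnorm(13))
  for (f in list(dispersion_difference_test, centroid_distance_test)) {
    r_ab <- f(a, b, n_perm = 199L, seed = 7L)
    r_ba <- f(b, a, n_perm = 199L, seed = 7L)
    expect_identical(r_ab$observed, r_ba$observed)
    expect_identical(r_ab$p_value, r_ba$p_value)
    expect_identical(r_ab$null_quantiles, r_ba$null_quantiles)
    # permuting input rows changes nothing
    r_shuf <- f(a[sample(nrow(a)), ], b[sample(nrow(b)), ], n_perm = 199L, seed = 7L)
    expect_identical(r_shuf$p_value, r_ab$p_value)
    # common translation changes nothing
    shift <- c(3.5, -2)
    r_tr <- f(sweep(a, 2L, shift, "+"), sweep(b, 2L, shift, "+"),
              n_perm = 199L, seed = 7L)
    expect_equal(r_tr$observed, r_ab$observed)
    expect_equal(r_tr$p_value, r_ab$p_value)
  }
  # the dispersion statistic is additionally rotation-invariant
  th <- 0.9
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2L)
  d0 <- dispersion_difference_test(a, b, n_perm = 199L, seed = 9L)
  d1 <- dispersion_difference_test(a %*% R, b %*% R, n_perm = 199L, seed = 9L)
  expect_equal(d1$observed, d0$observed)
})

test_that("null p-values are roughly uniform and power against clear signals is high", {
  # coarse uniformity: many null replicates, p should average near 0.5
  set.seed(31)
  pvals <- replicate(150, {
    a <- cbind(rnorm(12), rnorm(12)); b <- cbind(rnorm(12), rnorm(12))
    centroid_distance_test(a, b, n_perm = 99L, seed = sample.int(1e6, 1))$p_value
  })
  expect_gt(mean(pvals), 0.40)
  expect_lt(mean(pvals), 0.60)
  expect_gt(suppressWarnings(ks.test(pvals, "punif"))$p.value, 0.001)
  # strong signals are detected at the minimum achievable p
  set.seed(32)
  a <- cbind(rnorm(20), rnorm(20))
  b_shift <- sweep(cbind(rnorm(20), rnorm(20)), 2L, c(3, 0), "+")
  expect_equal(centroid_distance_test(a, b_shift, 999L, seed = 1L)$p_value, 0.001)
  b_wide <- cbind(rnorm(20, sd = 3), rnorm(20, sd = 3))
  expect_lte(dispersion_difference_test(a, b_wide, 999L, seed = 1L)$p_value, 0.05)
})
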