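test_that("the diamond configuration gives SEA = 2*pi/3 and SEAc = pi", {
  e <- fit_ellipse(cbind(c(1, -1, 0, 0), c(0, 0, 1, -1)))
  expect_equal(unname(e$centroid), c(0, 0))
  expect_equal(unname(e$cov), diag(c(2 / 3, 2 / 3)))
  expect_equal(e$sea, 2 * pi / 3)
  expect_equal(e$seac, pi)
  expect_false(e$degenerate)
})

test_that("collinear points are flagged degenerate with zero SEA; n < 3 errors", {
  e <- fit_ellipse(cbind(0:2, 0:2))
  expect_true(e$degenerate)
  expect_equal(e$eigenvalues[2L], 0)
  expect_equal(e$sea, 0)
  expect_error(fit_ellipse(cbind(c(0, 1), c(0, 1))), "insufficient sample")
  expect_error(scale_ellipse(e, "seac"), "degenerate")
})

test_that("SEA is invariant under translation/rotation and scales as s^2", {
  set.seed(41)
  for (rep in 1:5) {
    xy <- cbind(rnorm(12, -17, 0.4), rnorm(12, 14, 0.5))
    sea0 <- fit_ellipse(xy)$sea
    expect_equal(fit_ellipse(sweep(xy, 2L, c(3.2, -1.7), "+"))$sea, sea0)
    th <- runif(1, 0, 2 * pi)
    R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2L)
    expect_equal(fit_ellipse(xy %*% R)$sea, sea0)
    s <- runif(1, 0.5, 3)
    expect_equal(fit_ellipse(xy * s)$sea, s^2 * sea0)
    # the small-sample correction is exactly (n-1)/(n-2)
    e <- fit_ellipse(xy)
    expect_identical(e$seac, e$sea * (e$n - 1) / (e$n - 2))
  }
})

test_that("ellipse scaling follows the standard / SEAc / probability conventions", {
  set.seed(7)
  e <- fit_ellipse(cbind(rnorm(10), rnorm(10)))
  std <- scale_ellipse(e, "standard")
  expect_equal(std$area, e$sea)
  # probability level with chi-square quantile 1 coincides with the standard ellipse
  p1 <- pchisq(1, df = 2)
  pe <- scale_ellipse(e, "probability", p = p1)
  expect_equal(c(pe$a, pe$b), c(std$a, std$b))
  # 95% level scales axes by sqrt(qchisq(.95, 2)) ~ 2.4477
  p95 <- scale_ellipse(e, "p95")
  expect_equal(p95$a / std$a, sqrt(qchisq(0.95, 2)))
  expect_equal(sqrt(qchisq(0.95, 2)), 2.4477, tolerance = 1e-4)
  # SEAc mode: area equals SEAc; n = 3 scales axes by sqrt(2)
  expect_equal(scale_ellipse(e, "seac")$area, e$seac)
  e3 <- fit_ellipse(cbind(c(0, 1, 0), c(0, 0, 1)))
  expect_equal(scale_ellipse(e3, "seac")$a / scale_ellipse(e3, "standard")$a,
               sqrt(2))
  expect_error(scale_ellipse(e, "probability", p = 1.2), "in \\(0, 1\\)")
  expect_error(scale_ellipse(e, "probability", p = 0), "in \\(0, 1\\)")
})

test_that("intersection area matches circle oracles and is symmetric", {
  c0 <- make_scaled_ellipse(0, 0)
  c1 <- make_scaled_ellipse(1, 0)
  far <- make_scaled_ellipse(10, 0)
  expect_equal(intersection_area(c0, c0), pi, tolerance = 1e-4)
  expect_equal(intersection_area(c0, c1), circle_lens_area(1), tolerance = 5e-5)
  expect_identical(intersection_area(c0, far), 0)
  expect_equal(intersection_area(c0, c1), intersection_area(c1, c0))
  # containment: concentric similar ellipses intersect in the smaller one
  big <- make_scaled_ellipse(0, 0, a = 2, b = 1, angle = 0.4)
  small <- make_scaled_ellipse(0, 0, a = 1, b = 0.5, angle = 0.4)
  expect_equal(intersection_area(big, small), small$area, tolerance = 1e-4)
  expect_error(intersection_area(make_scaled_ellipse(a = 0), c0), "degenerate")
})

test_that("polygonal and Monte-Carlo intersection agree on random ellipse pairs", {
  set.seed(99)
  for (i in 1:20) {
    s1 <- random_scaled_ellipse()
    s2 <- random_scaled_ellipse()
    poly <- intersection_area(s1, s2)
    mc <- intersection_area(s1, s2, method = "monte_carlo", seed = i)
    expect_lt(abs(mc - poly), max(1e-3, 2e-3 * poly))
  }
})

test_that("the Jaccard overlap index obeys its bounds and symmetry", {
  c0 <- make_scaled_ellipse(0, 0)
  c1 <- make_scaled_ellipse(1, 0)
  expect_equal(overlap_index(c0, c0)$jaccard, 1, tolerance = 1e-4)
  expect_identical(overlap_index(c0, make_scaled_ellipse(10, 0))$jaccard, 0)
  lens <- circle_lens_area(1)
  expect_equal(overlap_index(c0, c1)$jaccard, lens / (2 * pi - lens),
               tolerance = 1e-4)
  set.seed(123)
  for (i in 1:10) {
    s1 <- random_scaled_ellipse()
    s2 <- random_scaled_ellipse()
    j12 <- overlap_index(s1, s2)$jaccard
    expect_gte(j12, 0); expect_lte(j12, 1)
    expect_equal(j12, overlap_index(s2, s1)$jaccard)
  }
})
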