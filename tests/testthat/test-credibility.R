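test_that("percentile interval matches the order-statistic closed form", {
  # draws 1..1000: type-7 percentile at 0.025 is 1 + 999 * 0.025 = 25.975
  ci <- credibility_interval(1:1000)
  expect_equal(ci$lower, 25.975)
  expect_equal(ci$upper, 975.025)
  expect_true(ci$excludes_zero)
})

test_that("constant draws give a degenerate interval", {
  ci <- credibility_interval(rep(3.2, 500))
  expect_equal(c(ci$lower, ci$upper), c(3.2, 3.2))
  expect_true(ci$excludes_zero)
  ci0 <- credibility_interval(rep(0, 500))
  expect_false(ci0$excludes_zero)
})

test_that("large normal samples reproduce +/- 1.96", {
  set.seed(42)
  ci <- credibility_interval(rnorm(1e5))
  expect_equal(ci$lower, -1.96, tolerance = 0.02)
  expect_equal(ci$upper, 1.96, tolerance = 0.02)
  expect_false(ci$excludes_zero)
})

test_that("fewer than 100 draws is an error", {
  expect_error(credibility_interval(rnorm(99)), "at least 100")
})

test_that("interval agrees with a brute-force sorted percentile", {
  # property: across random draw sets, each endpoint equals linear
  # interpolation of adjacent order statistics, hence sits within one
  # order-statistic step of the plain sorted percentile
  set.seed(7)
  for (rep in 1:50) {
    n <- sample(100:3000, 1)
    x <- switch(sample(3, 1), rnorm(n), rexp(n), stats::rcauchy(n))
    ci <- credibility_interval(x)
    s <- sort(x)
    for (p in c(0.025, 0.975)) {
      h <- 1 + (n - 1) * p
      manual <- s[floor(h)] + (h - floor(h)) * (s[min(floor(h) + 1, n)] - s[floor(h)])
      val <- if (p < 0.5) ci$lower else ci$upper
      expect_equal(val, manual, tolerance = 1e-12)
      expect_gte(val, s[floor(h)])
      expect_lte(val, s[min(floor(h) + 1, n)])
    }
  }
})

test_that("split R-hat is near 1 for iid draws and large for split chains", {
  set.seed(1)
  x <- matrix(rnorm(4000), ncol = 4)
  expect_lt(octhb:::split_rhat(x), 1.01)
  y <- x; y[, 1] <- y[, 1] + 5
  expect_gt(octhb:::split_rhat(y), 1.5)
})

test_that("derived seeds are deterministic, label-sensitive and in range", {
  expect_identical(derive_seed(1, "a", 2), derive_seed(1, "a", 2))
  expect_false(derive_seed(1, "a") == derive_seed(1, "b"))
  expect_false(derive_seed(1, "a") == derive_seed(2, "a"))
  s <- vapply(1:200, function(i) derive_seed(i, "x"), integer(1))
  expect_true(all(s >= 1 & s < 2^31 - 1))
})

test_that("beta mean/variance parameterization round-trips and validates", {
  sh <- octhb:::beta_shapes(0.7, 0.01)
  m <- sh[1] / sum(sh)
  v <- prod(sh) / (sum(sh)^2 * (sum(sh) + 1))
  expect_equal(unname(m), 0.7, tolerance = 1e-12)
  expect_equal(unname(v), 0.01, tolerance = 1e-12)
  expect_error(octhb:::beta_shapes(0.7, 0.3), "beta variance")
  expect_error(octhb:::beta_shapes(1.2, 0.01), "mean")
})
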