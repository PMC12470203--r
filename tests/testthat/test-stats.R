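test_that("pearson_matrix matches the brute-force product-moment oracle", {
  set.seed(101)
  for (i in 1:20) {
    n <- sample(4:10, 1)
    d <- data.frame(a = rnorm(n), b = rnorm(n), c = rnorm(n))
    if (i %% 3 == 0) d$a[sample(n, 1)] <- NA   # exercise pairwise deletion
    cm <- pearson_matrix(d)
    for (v1 in names(d)) for (v2 in names(d)) {
      if (v1 == v2) { expect_equal(cm$r[v1, v2], 1); next }
      expect_equal(cm$r[v1, v2], oracle_pearson(d[[v1]], d[[v2]]),
                   tolerance = 1e-12)
    }
  }
})

test_that("pearson_matrix p-values and stars behave", {
  d <- data.frame(x = 1:5, y = 2 * (1:5))
  cm <- pearson_matrix(d)
  expect_equal(cm$r["x", "y"], 1)
  expect_equal(cm$p["x", "y"], 0)
  expect_equal(cm$stars["x", "y"], "**")
  # the 4-point cross pattern
  d2 <- data.frame(x = c(1, 2, 3, 4), y = c(2, 1, 4, 3))
  cm2 <- pearson_matrix(d2)
  expect_equal(cm2$r["x", "y"], oracle_pearson(d2$x, d2$y), tolerance = 1e-12)
  # stars consistent with thresholds everywhere
  set.seed(5)
  d3 <- as.data.frame(matrix(rnorm(60), ncol = 4))
  cm3 <- pearson_matrix(d3)
  off <- upper.tri(cm3$p)
  expect_equal(cm3$stars[off] == "**", cm3$p[off] <= 0.01)
  expect_equal(cm3$stars[off] != "", cm3$p[off] <= 0.05)
})

test_that("constant variables yield NA correlations with a warning", {
  d <- data.frame(x = 1:6, y = rep(2, 6))
  expect_warning(cm <- pearson_matrix(d), "constant")
  expect_true(is.na(cm$r["x", "y"]))
})

test_that("linear_fit equals the normal-equations oracle", {
  f <- linear_fit(1:10, 3 * (1:10) + 1)
  expect_equal(f$slope, 3)
  expect_equal(f$intercept, 1)
  expect_equal(f$r_squared, 1)
  x <- c(0.5, 1.2, 2.0, 3.1, 4.4)
  y <- c(1.1, 0.4, 2.5, 2.2, 3.9)
  f2 <- linear_fit(x, y)
  o <- oracle_ols(x, y)
  expect_equal(unname(coef(f2)), unname(o), tolerance = 1e-12)
  expect_error(linear_fit(rep(1, 5), rnorm(5)), "constant")
  expect_error(linear_fit(1:2, 1:2), "at least 3")
})

test_that("the OLS confidence band is narrowest at the mean of x", {
  set.seed(8)
  x <- runif(30, 0, 10)
  y <- 2 + 0.5 * x + rnorm(30)
  f <- linear_fit(x, y)
  xs <- seq(0, 10, length.out = 201)
  pr <- predict(f, xs)
  width <- pr$upr - pr$lwr
  expect_equal(xs[which.min(width)], xs[which.min(abs(xs - mean(x)))])
})

test_that("threshold_fit recovers a known breakpoint and slope signs", {
  set.seed(42)
  x <- runif(60, 0.5, 3.5)
  y <- ifelse(x < 2.0, 1 + 0.4 * (x - 2.0), 1 - 0.3 * (x - 2.0)) +
    rnorm(60, 0, 0.05)
  tf <- threshold_fit(x, y)
  grid <- tf$search_grid
  step <- max(diff(grid))
  expect_lt(abs(tf$breakpoint - 2.0), step + 1e-12)
  expect_gt(tf$below$slope, 0)
  expect_lt(tf$above$slope, 0)
  # the searched breakpoint never does worse than the generating truth
  fixed <- threshold_fit(x, y, breakpoint = 2.0)
  expect_lte(tf$sse, fixed$sse)
})

test_that("threshold_fit contract: min points per side, tie to smaller break", {
  x <- 1:10
  y <- x * 0.5
  expect_error(threshold_fit(x, y, breakpoint = 9.5), "fewer than 3")
  expect_error(threshold_fit(x[1:5], y[1:5], breakpoint = 3), "at least 6")
  # perfectly linear data: all splits equal SSE ~ 0, tie -> smallest break
  tf <- threshold_fit(x, y)
  expect_equal(tf$breakpoint, min(tf$search_grid))
})

test_that("threshold_fit on breakless data stays consistent with a global line", {
  set.seed(9)
  x <- runif(40, 0, 10)
  y <- 1 + 0.7 * x + rnorm(40, 0, 0.3)
  tf <- threshold_fit(x, y)
  g <- linear_fit(x, y)
  expect_gte(tf$sse, 0)
  # two free segments can never fit worse than the single global line
  expect_lte(tf$sse, sum(residuals(g$model)^2))
  # and on breakless data both segments keep the global slope's sign
  expect_gt(tf$below$slope * g$slope, 0)
  expect_gt(tf$above$slope * g$slope, 0)
})

test_that("threshold_fit predict/coef are piecewise-consistent", {
  set.seed(2)
  x <- runif(30, 0, 4)
  y <- ifelse(x < 2, x, 4 - 0.5 * x) + rnorm(30, 0, 0.05)
  tf <- threshold_fit(x, y, breakpoint = 2)
  cf <- coef(tf)
  expect_equal(dim(cf), c(2L, 2L))
  expect_equal(predict(tf, 1.0), cf["below", "intercept"] + cf["below", "slope"])
  expect_equal(predict(tf, 3.0),
               cf["above", "intercept"] + 3 * cf["above", "slope"])
  expect_equal(tf$below$n + tf$above$n, 30)
})
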