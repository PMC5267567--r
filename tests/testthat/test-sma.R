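test_that("SMA fit equals the moment closed form on a perfect line", {
  x <- 1:5
  y <- 2 * x
  f <- sma_fit(x, y)
  expect_equal(f$slope, 2)
  expect_equal(f$intercept, 0)
  expect_equal(f$r_squared, 1)
  expect_lt(f$ci_high - f$ci_low, 1e-6)  # width 0 up to floating error
  expect_lt(f$p_slope_eq_1, 1e-10)
})

test_that("SMA slope and CI match independent moment and inversion oracles", {
  # moment oracle on a fixed 5-point set: x and y are permutations of 1:5,
  # so s_y / s_x = 1 exactly and the correlation is positive
  x <- c(1, 2, 3, 4, 5)
  y <- c(1, 3, 2, 5, 4)
  f <- sma_fit(x, y)
  r <- cor(x, y)
  expect_equal(f$slope, sign(r) * sd(y) / sd(x))
  expect_equal(f$slope, 1)
  expect_equal(f$r_squared, r^2)
  expect_equal(f$intercept, mean(y) - f$slope * mean(x))

  # CI verified by numerically inverting the slope test: testing slope = b
  # on (x, y) is testing slope = 1 on (b * x, y), so the p-value at each
  # CI bound must equal alpha
  set.seed(12)
  for (i in 1:20) {
    n <- sample(6:50, 1)
    xx <- rnorm(n)
    yy <- 0.5 + runif(1, 0.5, 2) * xx + rnorm(n, 0, runif(1, 0.2, 1))
    g <- sma_fit(xx, yy)
    p_at <- function(b) sma_fit(b * xx, yy)$p_slope_eq_1
    expect_equal(p_at(g$ci_low), g$alpha, tolerance = 1e-8)
    expect_equal(p_at(g$ci_high), g$alpha, tolerance = 1e-8)
  }
})

test_that("SMA degenerate and small inputs raise named errors", {
  expect_error(sma_fit(c(1, 1, 1), c(1, 2, 3)), "zero variance")
  expect_error(sma_fit(1:2, 2:3), "insufficient")
  expect_error(sma_fit(1:4, c(1, 2, NA, 4)), "non-finite")
})

test_that("through-origin SMA has the closed-form slope and flip invariance", {
  x <- c(1, 2, 4)
  expect_equal(sma_fit_through_origin(x, 1.5 * x)$slope, 1.5)

  f2 <- sma_fit_through_origin(c(1, 2), c(2, 3))
  expect_equal(f2$slope, sqrt(13 / 5))
  expect_true(is.na(f2$intercept))

  # flipping any single contrast pair jointly changes nothing
  set.seed(4)
  x <- rnorm(12)
  y <- 1.1 * x + rnorm(12, 0, 0.3)
  f <- sma_fit_through_origin(x, y)
  x[3] <- -x[3]
  y[3] <- -y[3]
  g <- sma_fit_through_origin(x, y)
  expect_equal(g$slope, f$slope)
  expect_equal(g$r_squared, f$r_squared)
  expect_equal(g$ci_low, f$ci_low)

  expect_error(sma_fit_through_origin(c(0, 0), c(1, 2)), "all x")
})

test_that("allometry verdict follows the CI position relative to 1", {
  # the published whole-order intervals: mass vs carapace length
  expect_equal(classify_allometry(list(ci_low = 1.002, ci_high = 1.135)),
               "rensch_rule")
  expect_equal(classify_allometry(list(ci_low = 0.997, ci_high = 1.120)),
               "isometry")
  expect_equal(classify_allometry(list(ci_low = 0.70, ci_high = 0.95)),
               "converse")
})

test_that("OLS fit matches the normal-equations oracle", {
  x <- 1:6
  f <- ols_fit(x, x / 3)
  expect_equal(f$slope, 1 / 3)
  expect_equal(f$r_squared, 1)
  expect_equal(f$rss, 0, tolerance = 1e-20)

  set.seed(9)
  x <- rnorm(10)
  y <- 2 + 0.4 * x + rnorm(10, 0, 0.2)
  f <- ols_fit(x, y)
  b <- cov(x, y) / var(x)             # normal equations
  a <- mean(y) - b * mean(x)
  expect_equal(f$slope, b)
  expect_equal(f$intercept, a)
  expect_equal(f$rss, sum((y - a - b * x)^2))
  # shift equivariance: adding a constant to y moves the intercept only
  g <- ols_fit(x, y + 5)
  expect_equal(g$slope, f$slope)
  expect_equal(g$intercept, f$intercept + 5)
})

test_that("Chow test matches the nested-model F and detects breaks", {
  set.seed(5)
  xa <- rnorm(20)
  ya <- 1 + 0.3 * xa + rnorm(20, 0, 0.2)
  xb <- rnorm(25)
  yb <- 0.8 + 0.35 * xb + rnorm(25, 0, 0.2)
  ct <- chow_test(xa, ya, xb, yb)
  grp <- factor(rep(c("a", "b"), c(20, 25)))
  an <- anova(lm(c(ya, yb) ~ c(xa, xb)),
              lm(c(ya, yb) ~ c(xa, xb) * grp))
  expect_equal(ct$statistic, an$F[2])
  expect_equal(ct$p_value, an$`Pr(>F)`[2])

  # a group compared with its exact copy shows no structural break
  same <- chow_test(xa, ya, xa, ya)
  expect_equal(same$statistic, 0, tolerance = 1e-8)
  expect_equal(same$p_value, 1, tolerance = 1e-6)

  # very different slopes with tiny noise separate completely
  x <- seq(1, 3, length.out = 30)
  sep <- chow_test(x, 0.30 * x + rnorm(30, 0, 1e-4),
                   x, 0.60 * x + rnorm(30, 0, 1e-4))
  expect_lt(sep$p_value, 1e-6)
})

test_that("slope-equality t-test is null-calibrated and detects differences", {
  x <- seq(1, 3, length.out = 40)
  st <- slope_equality_test(x, 0.30 * x + rnorm(40, 0, 1e-4),
                            x, 0.60 * x + rnorm(40, 0, 1e-4))
  expect_lt(st$p_value, 1e-6)
  set.seed(8)
  ps <- replicate(300, {
    xa <- rnorm(25); xb <- rnorm(25)
    slope_equality_test(xa, 0.3 * xa + rnorm(25, 0, 0.1),
                        xb, 0.3 * xb + rnorm(25, 0, 0.1))$p_value
  })
  expect_lt(abs(mean(ps < 0.05) - 0.05), 0.04)
})

test_that("SMA invariance properties hold over randomized inputs", {
  set.seed(77)
  for (i in 1:30) {
    n <- sample(5:40, 1)
    x <- rnorm(n)
    y <- runif(1, 0.5, 2) * x + rnorm(n, 0, runif(1, 0.1, 1))
    f <- sma_fit(x, y)
    # axis-swap reciprocity
    expect_equal(sma_fit(y, x)$slope, 1 / f$slope)
    # scale equivariance: y * c multiplies the slope by c
    expect_equal(sma_fit(x, 3 * y)$slope, 3 * f$slope)
    # common log-base change (x, y both scaled) leaves everything invariant
    g <- sma_fit(x * log(10), y * log(10))
    expect_equal(g$slope, f$slope)
    expect_equal(g$r_squared, f$r_squared)
    expect_equal(g$p_slope_eq_1, f$p_slope_eq_1)
    # |SMA slope| >= |OLS slope| since |b_sma| = |b_ols| / |r|
    expect_gte(abs(f$slope) + 1e-12, abs(ols_fit(x, y)$slope))
  }
})

test_that("SMA CI attains nominal coverage for the true SMA slope", {
  set.seed(42)
  b_true <- sqrt(5)  # sd(2x + e)/sd(x) with sd(e) = 1
  covered <- replicate(400, {
    x <- rnorm(100)
    y <- 2 * x + rnorm(100)
    f <- sma_fit(x, y)
    f$ci_low <= b_true && b_true <= f$ci_high
  })
  expect_gt(mean(covered), 0.91)
  expect_lt(mean(covered), 0.99)
})
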