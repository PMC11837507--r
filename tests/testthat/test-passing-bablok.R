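test_that("both estimators recover exact lines", {
  for (m in c("classical", "equivariant")) {
    f <- passing_bablok(1:3, 1:3, method = m, boot = 0)
    expect_equal(coef(f), c(intercept = 0, slope = 1))
    x <- seq(0, 5, length.out = 50)
    f2 <- passing_bablok(x, 2 * x + 1, method = m, boot = 0)
    expect_equal(coef(f2), c(intercept = 1, slope = 2), tolerance = 1e-12)
  }
  f3 <- passing_bablok(c(1, 2, 3), c(2, 3, 5), method = "classical", boot = 0)
  # pairwise slopes {1, 1.5, 2}; median residual at slope 1.5 is 0.5
  expect_equal(coef(f3), c(intercept = 0.5, slope = 1.5))
  expect_error(passing_bablok(c(1, 1, 1), c(1, 2, 3), boot = 0), "identical")
})

test_that("classical estimator matches brute-force enumeration on small n", {
  set.seed(501)
  n_match <- 0L
  for (i in 1:300) {
    n <- sample(3:6, 1)
    # mix of continuous values, integer grids (ties, exact -1 slopes)
    x <- if (i %% 2) round(runif(n, -3, 3)) else runif(n, -3, 3)
    y <- if (i %% 3) round(runif(n, -3, 3)) else runif(n, -3, 3)
    if (length(unique(x)) == 1) next
    oracle <- pb_brute_force(x, y)
    if (is.na(oracle["slope"])) next
    fit <- passing_bablok(x, y, method = "classical", boot = 0)
    expect_equal(unname(coef(fit)["slope"]), unname(oracle["slope"]),
                 tolerance = 1e-12)
    expect_equal(unname(coef(fit)["intercept"]), unname(oracle["intercept"]),
                 tolerance = 1e-12)
    n_match <- n_match + 1L
  }
  expect_gt(n_match, 200L)
})

test_that("the angle-median estimator is equivariant under axis exchange", {
  # exact when all pairwise slopes share a sign (no wrap across the +-pi/2
  # angle cut); here both series are strictly increasing, so they do
  set.seed(502)
  for (i in 1:20) {
    n <- sample(5:30, 1)
    x <- cumsum(runif(n, 0.1, 1))
    y <- cumsum(runif(n, 0.1, 1))
    f <- passing_bablok(x, y, method = "equivariant", boot = 0)
    g <- passing_bablok(y, x, method = "equivariant", boot = 0)
    expect_equal(g$slope, 1 / f$slope, tolerance = 1e-10)
    # and the fitted line maps to its inverse
    expect_equal(g$intercept, -f$intercept / f$slope, tolerance = 1e-8)
  }
})

test_that("both estimators are scale-equivariant in y", {
  # positive-association data: no pairwise slope crosses the classical
  # estimator's -1 exclusion under scaling. 19 points give an odd number of
  # pairs, so the angle median is a single order statistic and exact; for an
  # even pair count it interpolates between two angles and is equivariant
  # only to ~1e-5
  set.seed(503)
  x <- cumsum(runif(19, 0.1, 1))
  y <- cumsum(runif(19, 0.1, 1))
  for (m in c("classical", "equivariant")) {
    f <- passing_bablok(x, y, method = m, boot = 0)
    g <- passing_bablok(x, 5 * y, method = m, boot = 0)
    expect_equal(g$slope, 5 * f$slope, tolerance = 1e-12)
    expect_equal(g$intercept, 5 * f$intercept, tolerance = 1e-12)
  }
  xe <- cumsum(runif(20, 0.1, 1))
  ye <- cumsum(runif(20, 0.1, 1))
  fe <- passing_bablok(xe, ye, method = "equivariant", boot = 0)
  ge <- passing_bablok(xe, 5 * ye, method = "equivariant", boot = 0)
  expect_equal(ge$slope, 5 * fe$slope, tolerance = 1e-4)
})

test_that("Pearson r is invariant to sign-preserving affine transforms", {
  set.seed(504)
  x <- runif(30); y <- x + rnorm(30, 0, 0.1)
  r1 <- passing_bablok(x, y, boot = 0)$pearson_r
  r2 <- passing_bablok(3 * x + 2, 0.5 * y - 1, boot = 0)$pearson_r
  expect_equal(r1, r2, tolerance = 1e-12)
})

test_that("bootstrap CIs are degenerate on noiseless data and seed-stable", {
  x <- seq(1, 5, length.out = 12)
  f <- suppressWarnings(passing_bablok(x, x, boot = 99, seed = 1))
  expect_equal(f$slope_ci, c(1, 1))
  expect_equal(f$intercept_ci, c(0, 0))

  set.seed(600)
  x <- runif(30); y <- 0.8 * x + rnorm(30, 0, 0.05)
  a <- passing_bablok(x, y, boot = 199, seed = 42)
  b <- passing_bablok(x, y, boot = 199, seed = 42)
  expect_identical(a$slope_ci, b$slope_ci)
  expect_identical(a$intercept_ci, b$intercept_ci)
})

test_that("bootstrap slope CI covers the generating slope", {
  # y = 0.81 x + 0.01 + N(0, 0.02); checked over 20 replicate fits
  set.seed(700)
  covered <- 0L
  for (r in 1:20) {
    x <- runif(120, 0, 0.5)
    y <- 0.81 * x + 0.01 + rnorm(120, 0, 0.02)
    f <- passing_bablok(x, y, boot = 399, seed = 700 + r)
    if (f$slope_ci[1] <= 0.81 && 0.81 <= f$slope_ci[2]) covered <- covered + 1L
  }
  expect_gte(covered, 18L)
})

test_that("CI interpretation flags proportional and constant differences", {
  mk <- function(sci, ici) {
    structure(list(slope_ci = sci, intercept_ci = ici), class = "pb_fit")
  }
  f1 <- interpret_comparison(mk(c(0.76, 0.87), c(0.001, 0.019)))
  expect_true(f1$proportional_difference)
  expect_true(f1$constant_difference)
  f2 <- interpret_comparison(mk(c(0.95, 1.02), c(-0.0001, 0.000)))
  expect_false(f2$proportional_difference)
  expect_false(f2$constant_difference)
  # closed interval: a bound exactly touching the null value is no difference
  f3 <- interpret_comparison(mk(c(0.9, 1.0), c(0, 0.01)))
  expect_false(f3$proportional_difference)
  expect_false(f3$constant_difference)
})

test_that("pb_fit methods predict and summarize coherently", {
  f <- passing_bablok(c(1, 2, 3, 4), c(2.1, 2.9, 4.2, 5.0), boot = 0)
  expect_equal(predict(f, newdata = 0), f$intercept)
  expect_equal(residuals(f), f$y - predict(f))
  expect_output(print(f), "Passing-Bablok")
})

test_that("two-group ANOVA matches the closed-form oracle and edge cases", {
  t1 <- genus_group_test(c(1, 2, 3), c(2, 3, 4))
  oracle <- anova_two_group_oracle(c(1, 2, 3), c(2, 3, 4))
  expect_equal(t1$statistic, unname(oracle["F"]))
  expect_equal(t1$statistic, 1.5)
  expect_equal(t1$p.value, unname(oracle["p"]), tolerance = 1e-12)
  expect_equal(round(t1$p.value, 3), 0.288)

  same <- genus_group_test(c(1, 1, 1), c(1, 1, 1))
  expect_equal(same$statistic, 0)
  expect_equal(same$p.value, 1)

  sep <- genus_group_test(c(0, 0, 0), c(1, 1, 1))
  expect_true(is.finite(sep$statistic))
  expect_equal(sep$p.value, 0)

  set.seed(505)
  for (i in 1:10) {
    a <- rnorm(7); b <- rnorm(7, 0.5)
    got <- genus_group_test(a, b)
    want <- anova_two_group_oracle(a, b)
    expect_equal(got$statistic, unname(want["F"]), tolerance = 1e-10)
    expect_equal(got$p.value, unname(want["p"]), tolerance = 1e-10)
  }
})

test_that("significance tiers follow the ridgeline annotation convention", {
  expect_equal(significance_tier(c(0.0005, 0.005, 0.03, 0.08, 0.5)),
               c("***", "**", "*", "•", ""))
})
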