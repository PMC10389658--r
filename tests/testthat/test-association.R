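# Linear associations, chi-squared trait tests, group summaries, two-group
# comparisons and the correlogram.

test_that("linear association recovers exact and degenerate fits", {
  x <- 1:5
  f <- linear_assoc(x, 2 * x + 1)
  expect_equal(f$slope, 2, tolerance = 1e-12)
  expect_equal(f$intercept, 1, tolerance = 1e-12)
  expect_equal(f$r2, 1, tolerance = 1e-12)
  # constant response: slope 0, r2 0 by convention
  fc <- linear_assoc(x, rep(3, 5))
  expect_equal(fc$slope, 0)
  expect_equal(fc$r2, 0)
  expect_error(linear_assoc(rep(1, 5), x), "zero variance")
  expect_error(linear_assoc(1:2, 1:2), "at least 3")
})

test_that("linear association matches the normal-equation oracle", {
  x <- c(1.2, 2.7, 3.1, 4.9, 6.0, 7.4)
  y <- c(2.3, 3.9, 3.1, 6.8, 6.1, 9.0)
  f <- linear_assoc(x, y)
  # closed-form normal equations
  sxx <- sum((x - mean(x))^2)
  sxy <- sum((x - mean(x)) * (y - mean(y)))
  slope <- sxy / sxx
  intercept <- mean(y) - slope * mean(x)
  r <- sxy / sqrt(sxx * sum((y - mean(y))^2))
  expect_equal(f$slope, slope, tolerance = 1e-9)
  expect_equal(f$intercept, intercept, tolerance = 1e-9)
  expect_equal(f$r2, r^2, tolerance = 1e-9)
  # two-sided slope test from the t distribution
  n <- length(x)
  se <- sqrt(sum((y - intercept - slope * x)^2) / (n - 2) / sxx)
  expect_equal(f$p, 2 * pt(abs(slope / se), df = n - 2, lower.tail = FALSE),
               tolerance = 1e-9)
  # missing pairs are dropped and counted
  f2 <- linear_assoc(c(x, NA), c(y, 1))
  expect_equal(f2$n, 6)
  expect_equal(f2$n_dropped, 1)
})

test_that("dichotomization splits at the median or a threshold", {
  expect_identical(dichotomize(c(1, 2, 3, 4)), c(FALSE, FALSE, TRUE, TRUE))
  expect_identical(dichotomize(c(-1, 1), rule = "threshold", threshold = 0),
                   c(FALSE, TRUE))
  # exact-median ties go to the lower group
  expect_identical(dichotomize(c(1, 2, 2, 3)), c(FALSE, FALSE, FALSE, TRUE))
  expect_error(dichotomize(c(5, 5, 5)), "all values equal")
})

test_that("chi-squared presence test matches the closed form and is symmetric", {
  trait <- rep(c(TRUE, FALSE), each = 10)
  env <- rep(c(TRUE, FALSE), each = 10)
  res <- chi_square_presence(trait, env)
  expect_equal(res$chi2, 20, tolerance = 1e-12)   # [[10,0],[0,10]]
  expect_lt(res$p, 1e-4)
  expect_false(res$correction_applied)
  # perfectly proportional table has statistic 0
  t2 <- c(rep(TRUE, 15), rep(FALSE, 30))
  e2 <- c(rep(TRUE, 5), rep(FALSE, 10), rep(TRUE, 10), rep(FALSE, 20))
  expect_equal(chi_square_presence(t2, e2)$chi2, 0, tolerance = 1e-12)
  # transposition symmetry
  set.seed(8)
  a <- runif(80) < 0.4; b <- runif(80) < 0.6
  expect_equal(chi_square_presence(a, b)$chi2, chi_square_presence(b, a)$chi2,
               tolerance = 1e-12)
  # low expected counts are flagged
  small <- chi_square_presence(c(rep(TRUE, 4), rep(FALSE, 6)),
                               c(TRUE, FALSE, TRUE, FALSE, rep(c(TRUE, FALSE), 3)))
  expect_true(small$expected_minimum < 5 && small$low_expected)
  # zero marginal rejected
  expect_error(chi_square_presence(rep(TRUE, 10), rep(c(TRUE, FALSE), 5)),
               "marginal")
})

test_that("group summaries give Tukey boxplot statistics per level", {
  v <- c(1, 2, 3, 4, 100)
  g <- group_summary(v, rep(1L, 5))
  expect_equal(g$n, 5L)
  expect_equal(g$median, 3)
  expect_equal(g$q1, 2)
  expect_equal(g$q3, 4)
  expect_identical(g$outliers[[1]], 100)   # beyond q3 + 1.5 IQR = 7
  expect_equal(g$whisker_hi, 4)
  # single-value level
  g1 <- group_summary(5, 0L)
  expect_equal(g1$median, 5)
  expect_equal(g1$q3 - g1$q1, 0)
  # empty levels are omitted
  g2 <- group_summary(c(1, 2), c(0L, 0L))
  expect_equal(nrow(g2), 1)
  expect_error(group_summary(1:2, c(1L, 7L)), "0-3")
})

test_that("two-group comparison uses Welch's unequal-variance test", {
  same <- two_group_means(c(1, 2, 3, 1, 2, 3), rep(c(TRUE, FALSE), each = 3))
  expect_equal(same$mean_true, same$mean_false)
  expect_equal(same$p, 1)
  sep <- two_group_means(c(0, 0, 0, 0, 10, 10, 10, 10),
                         rep(c(FALSE, TRUE), each = 4))
  expect_equal(sep$mean_true, 10)
  expect_equal(sep$mean_false, 0)
  expect_lt(sep$p, 0.01)
  # Welch formula oracle on random normal groups
  set.seed(99)
  a <- rnorm(20, 1); b <- rnorm(20, 0)
  res <- two_group_means(c(a, b), rep(c(TRUE, FALSE), each = 20))
  va <- var(a) / 20; vb <- var(b) / 20
  tstat <- (mean(a) - mean(b)) / sqrt(va + vb)
  dfw <- (va + vb)^2 / (va^2 / 19 + vb^2 / 19)
  expect_equal(res$p, 2 * pt(abs(tstat), dfw, lower.tail = FALSE),
               tolerance = 1e-9)
  # tiny group: means reported, no p
  tiny <- two_group_means(c(1, 5, 6, 7), c(TRUE, FALSE, FALSE, FALSE))
  expect_equal(tiny$mean_true, 1)
  expect_true(is.na(tiny$p))
  expect_error(two_group_means(1:3, rep(TRUE, 3)), "non-empty")
})

test_that("the correlogram equals per-pair Pearson coefficients", {
  expect_equal(correlogram(data.frame(a = 1:5, b = 1:5))["a", "b"], 1)
  expect_equal(correlogram(data.frame(a = 1:5, b = -(1:5)))["a", "b"], -1)
  set.seed(3)
  df <- data.frame(x = rnorm(8), y = rnorm(8), z = rnorm(8))
  df$y[3] <- NA
  r <- correlogram(df)
  expect_true(isSymmetric(r))
  expect_equal(diag(r), c(x = 1, y = 1, z = 1))
  for (i in c("x", "y", "z")) {
    for (j in c("x", "y", "z")) {
      keep <- complete.cases(df[[i]], df[[j]])
      expect_equal(r[i, j], cor(df[[i]][keep], df[[j]][keep]), tolerance = 1e-12)
    }
  }
  # zero-variance columns are dropped with a warning
  df$c0 <- 1
  expect_warning(r2 <- correlogram(df), "zero-variance")
  expect_false("c0" %in% colnames(r2))
  # r2 of linear_assoc equals the squared correlogram entry
  f <- linear_assoc(df$x, df$z)
  expect_equal(f$r2, r["x", "z"]^2, tolerance = 1e-12)
  # dot-style rendering builds without evaluation errors
  expect_s3_class(plot_correlogram(r), "ggplot")
})
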