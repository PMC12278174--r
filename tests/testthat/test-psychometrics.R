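test_that("descriptives report the adjusted sample moments", {
  d <- describe(c(1, 2, 3))
  expect_equal(d$mean, 2)
  expect_equal(d$skewness, 0)
  expect_true(is.na(d$excess_kurtosis))  # needs n >= 4

  d2 <- describe(c(2, 4))
  expect_equal(d2$mean, 3)
  expect_equal(d2$sd, sqrt(2))
  expect_true(is.na(d2$skewness))

  # adjusted-moment formula oracle, evaluated directly
  x <- c(1, 1, 4, 4, 10)
  n <- length(x)
  m2 <- mean((x - mean(x))^2)
  g1 <- mean((x - mean(x))^3) / m2^1.5
  g2 <- mean((x - mean(x))^4) / m2^2 - 3
  G1 <- g1 * sqrt(n * (n - 1)) / (n - 2)
  G2 <- ((n + 1) * g2 + 6) * (n - 1) / ((n - 2) * (n - 3))
  d3 <- describe(x)
  expect_equal(d3$skewness, G1, tolerance = 1e-12)
  expect_equal(d3$excess_kurtosis, G2, tolerance = 1e-12)
  # independent implementation check (e1071 type-2 estimators)
  expect_equal(d3$skewness, e1071::skewness(x, type = 2), tolerance = 1e-12)
  expect_equal(d3$excess_kurtosis, e1071::kurtosis(x, type = 2),
               tolerance = 1e-12)
  expect_error(describe(numeric(0)), "non-missing")
})

test_that("floor and ceiling proportions count exact extremes", {
  fc0 <- floor_ceiling(c(10, 50, 90), 0, 100)
  expect_equal(c(fc0$floor_prop, fc0$ceiling_prop), c(0, 0))

  fc <- floor_ceiling(c(0, 50, 100), 0, 100)
  expect_equal(fc$floor_prop, 1 / 3)
  expect_equal(fc$ceiling_prop, 1 / 3)
  expect_equal(fc$n_at_min_observed, 1L)
  expect_equal(fc$n_at_max_observed, 1L)

  # a 100-score cohort with 3 at the observed maximum (below the possible
  # ceiling) and 1 at the observed minimum
  scores <- c(77.33, rep(98, 3), seq(80, 97, length.out = 96))
  fc2 <- floor_ceiling(scores, 0, 100)
  expect_equal(fc2$floor_prop, 0)
  expect_equal(fc2$ceiling_prop, 0)
  expect_equal(fc2$n_at_max_observed, 3L)
  expect_equal(fc2$n_at_min_observed, 1L)

  expect_error(floor_ceiling(c(-1, 50), 0, 100), "outside")
})

test_that("Spearman correlation equals Pearson on midranks with a t p-value", {
  expect_equal(assoc_spearman(1:3, 1:3)$estimate, 1)
  expect_equal(assoc_spearman(1:3, 3:1)$estimate, -1)

  set.seed(14)
  x <- sample(rep(1:6, 4))  # heavy ties
  y <- x + rnorm(24)
  res <- assoc_spearman(x, y)
  expect_equal(res$estimate, stats::cor(rank(x), rank(y)), tolerance = 1e-12)
  ct <- suppressWarnings(stats::cor.test(x, y, method = "spearman",
                                         exact = FALSE))
  expect_equal(res$estimate, unname(ct$estimate), tolerance = 1e-12)
  expect_equal(res$p_value, ct$p.value, tolerance = 1e-10)
  expect_error(assoc_spearman(c(1, 1, 1), 1:3), "constant")
})

test_that("Pearson correlation matches the covariance formula and cor.test", {
  expect_equal(assoc_pearson(1:5, 2 * (1:5) + 1)$estimate, 1)
  expect_equal(assoc_pearson(1:5, -(1:5))$estimate, -1)

  set.seed(3)
  x <- rnorm(5)
  y <- rnorm(5)
  res <- assoc_pearson(x, y)
  r_direct <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(res$estimate, r_direct, tolerance = 1e-12)
  ct <- stats::cor.test(x, y)
  expect_equal(res$p_value, ct$p.value, tolerance = 1e-12)
  expect_error(assoc_pearson(rep(1, 5), 1:5), "zero-variance")
})

test_that("rank-sum test: exact enumeration, symmetry, and approximation", {
  # enumerating all 6 rank assignments of {1,2} vs {3,4}: 2 of 6 as extreme
  expect_equal(rank_sum_test(c(1, 2), c(3, 4))$p_value, 1 / 3)
  # group swap leaves the p-value unchanged
  set.seed(8)
  a <- rnorm(6)
  b <- rnorm(9) + 1
  expect_equal(rank_sum_test(a, b)$p_value, rank_sum_test(b, a)$p_value)
  # exact path agrees with the reference implementation
  expect_equal(rank_sum_test(a, b)$p_value, stats::wilcox.test(a, b)$p.value,
               tolerance = 1e-12)
  # normal approximation within 0.02 of exact enumeration at n = 8 per group
  for (s in 1:10) {
    set.seed(100 + s)
    a8 <- rnorm(8)
    b8 <- rnorm(8) + runif(1, -1, 1)
    exact <- rank_sum_test(a8, b8)
    approx <- rank_sum_test(a8, b8, exact_max = 0)
    expect_equal(exact$method, "exact")
    expect_equal(approx$method, "normal_approx")
    expect_lt(abs(exact$p_value - approx$p_value), 0.02)
  }
  # tie-corrected normal path agrees with the reference implementation
  at <- c(a, a[1])
  expect_equal(rank_sum_test(at, b)$p_value,
               suppressWarnings(stats::wilcox.test(at, b)$p.value),
               tolerance = 1e-12)
  # degenerate input: all values identical
  expect_warning(res <- rank_sum_test(rep(2, 5), rep(2, 4)), "identical")
  expect_equal(res$p_value, 1)
})

test_that("simple regression matches least squares and ties to Pearson", {
  fit <- simple_ols(1:10, 2 * (1:10) + 1)
  expect_equal(fit$slope, 2)
  expect_equal(fit$intercept, 1)
  expect_equal(fit$r_squared, 1)

  flat <- simple_ols(1:10, rep(5, 10))
  expect_equal(flat$slope, 0)
  expect_equal(flat$r_squared, 0)

  set.seed(11)
  x <- rnorm(80)
  y <- 0.3 * x + rnorm(80)
  fit2 <- simple_ols(x, y)
  expect_equal(fit2$df_den, 78L)
  lmf <- stats::lm(y ~ x)
  expect_equal(fit2$slope, unname(stats::coef(lmf)[2]), tolerance = 1e-12)
  expect_equal(fit2$intercept, unname(stats::coef(lmf)[1]), tolerance = 1e-12)
  sm <- summary(lmf)
  expect_equal(fit2$r_squared, sm$r.squared, tolerance = 1e-12)
  expect_equal(fit2$f_statistic, unname(sm$fstatistic[1]), tolerance = 1e-10)
  # R^2 is the squared Pearson correlation; the F test matches its t test
  pr <- assoc_pearson(x, y)
  expect_equal(fit2$r_squared, pr$estimate^2, tolerance = 1e-12)
  expect_equal(fit2$p_value, pr$p_value, tolerance = 1e-10)
  expect_error(simple_ols(rep(1, 5), rnorm(5)), "zero variance")
})

test_that("z-scoring standardizes against reference moments", {
  expect_equal(zscore(5, 5, 2), 0)
  expect_equal(zscore(1, 0, 1), 1)
  expect_equal(zscore(0.43, 0, 1), 0.43)
  expect_equal(zscore(c(2, 4), 3, 1), c(-1, 1))
  expect_error(zscore(1, 0, 0), "ref_sd")
})

test_that("estimates are invariant to order and admissible transforms", {
  set.seed(21)
  x <- rnorm(40)
  y <- 0.4 * x + rnorm(40)
  perm <- sample(40)
  expect_equal(assoc_spearman(x, y)$estimate,
               assoc_spearman(x[perm], y[perm])$estimate, tolerance = 1e-12)
  expect_equal(assoc_pearson(x, y)$estimate,
               assoc_pearson(x[perm], y[perm])$estimate, tolerance = 1e-12)
  # positive affine transforms leave both correlations unchanged
  expect_equal(assoc_pearson(3 * x + 2, 0.5 * y - 1)$estimate,
               assoc_pearson(x, y)$estimate, tolerance = 1e-12)
  # Spearman survives any strictly monotone transform
  expect_equal(assoc_spearman(exp(x), y^3 + 5 * y)$estimate,
               assoc_spearman(x, y)$estimate, tolerance = 1e-12)
})
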