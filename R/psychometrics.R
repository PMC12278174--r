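#' Descriptive summary with skew and kurtosis
#'
#' Mean, sample SD (n-1 denominator), range, the adjusted Fisher-Pearson
#' skewness G1, and the sample excess kurtosis G2 (both zero in expectation
#' for normal data). Skewness needs n >= 3 and kurtosis n >= 4; below those
#' sizes the fields are `NA`.
#'
#' @param values Numeric vector; `NA`s are dropped.
#' @return A one-row tibble: `n`, `mean`, `sd`, `minimum`, `maximum`,
#'   `skewness`, `excess_kurtosis`.
#' @examples
#' describe(c(1, 1, 4, 4, 10))
#' @export
describe <- function(values) {
  values <- values[!is.na(values)]
  n <- length(values)
  if (n == 0L) abort("`values` has no non-missing entries.")
  m <- mean(values)
  ctr <- values - m
  m2 <- mean(ctr^2)
  skew <- NA_real_
  kurt <- NA_real_
  if (n >= 3L && m2 > 0) {
    g1 <- mean(ctr^3) / m2^1.5
    skew <- g1 * sqrt(n * (n - 1)) / (n - 2)
  }
  if (n >= 4L && m2 > 0) {
    g2 <- mean(ctr^4) / m2^2 - 3
    kurt <- ((n + 1) * g2 + 6) * (n - 1) / ((n - 2) * (n - 3))
  }
  tibble(
    n = n,
    mean = m,
    sd = if (n >= 2L) stats::sd(values) else NA_real_,
    minimum = min(values),
    maximum = max(values),
    skewness = skew,
    excess_kurtosis = kurt
  )
}

#' Floor and ceiling effects
#'
#' Proportion of scores exactly at the lowest and highest *possible* values
#' of the scale, plus the counts at the *observed* extremes (useful when no
#' one reaches the theoretical bounds).
#'
#' @param values Numeric scores; `NA`s are dropped.
#' @param lowest_possible,highest_possible The scale bounds.
#' @return A one-row tibble: `floor_prop`, `ceiling_prop`,
#'   `n_at_min_observed`, `n_at_max_observed`, `min_observed`,
#'   `max_observed`, `n`.
#' @export
floor_ceiling <- function(values, lowest_possible, highest_possible) {
  stopifnot(lowest_possible < highest_possible)
  values <- values[!is.na(values)]
  if (length(values) == 0L) abort("`values` has no non-missing entries.")
  if (any(values < lowest_possible | values > highest_possible)) {
    abort("Some values fall outside the possible score range.")
  }
  tibble(
    floor_prop = mean(values == lowest_possible),
    ceiling_prop = mean(values == highest_possible),
    n_at_min_observed = sum(values == min(values)),
    n_at_max_observed = sum(values == max(values)),
    min_observed = min(values),
    max_observed = max(values),
    n = length(values)
  )
}

assoc_result <- function(statistic_name, estimate, p_value, n_used) {
  tibble(statistic_name = statistic_name, estimate = estimate,
         p_value = p_value, n_used = as.integer(n_used))
}

drop_incomplete_pairs <- function(x, y) {
  if (length(x) != length(y)) abort("`x` and `y` must have equal length.")
  keep <- !is.na(x) & !is.na(y)
  list(x = x[keep], y = y[keep])
}

#' Spearman rank correlation
#'
#' Rank correlation with average ranks for ties (the Pearson correlation of
#' the midranks), with a two-sided p-value from the t approximation on
#' n - 2 degrees of freedom.
#'
#' @param x,y Numeric vectors of equal length; incomplete pairs are dropped.
#' @return A one-row tibble: `statistic_name`, `estimate`, `p_value`,
#'   `n_used`.
#' @export
assoc_spearman <- function(x, y) {
  d <- drop_incomplete_pairs(x, y)
  n <- length(d$x)
  if (n < 3L) abort("Spearman correlation needs at least 3 complete pairs.")
  rx <- rank(d$x)
  ry <- rank(d$y)
  if (stats::var(rx) == 0 || stats::var(ry) == 0) {
    abort("Spearman correlation is undefined when either variable's ranks are constant.")
  }
  rho <- stats::cor(rx, ry)
  assoc_result("spearman_rho", rho, cor_t_pvalue(rho, n), n)
}

# Two-sided p for a correlation via t = r * sqrt((n-2)/(1-r^2)).
cor_t_pvalue <- function(r, n) {
  if (abs(r) >= 1) return(0)
  t <- r * sqrt((n - 2) / (1 - r^2))
  2 * pt(-abs(t), df = n - 2)
}

#' Pearson product-moment correlation
#'
#' Two-sided p-value from the t distribution on n - 2 degrees of freedom.
#'
#' @inheritParams assoc_spearman
#' @return A one-row tibble: `statistic_name`, `estimate`, `p_value`,
#'   `n_used`.
#' @export
assoc_pearson <- function(x, y) {
  d <- drop_incomplete_pairs(x, y)
  n <- length(d$x)
  if (n < 3L) abort("Pearson correlation needs at least 3 complete pairs.")
  if (stats::var(d$x) == 0 || stats::var(d$y) == 0) {
    abort("Pearson correlation is undefined for a zero-variance variable.")
  }
  r <- stats::cor(d$x, d$y)
  assoc_result("pearson_r", r, cor_t_pvalue(r, n), n)
}

#' Wilcoxon rank-sum (Mann-Whitney) test
#'
#' Two-sided test of a location difference between two independent groups.
#' When both groups have at most `exact_max` observations and there are no
#' ties, the p-value is exact, obtained by enumerating every assignment of
#' the pooled ranks to the first group; otherwise a normal approximation
#' with tie-corrected variance and a continuity correction is used. The
#' estimate reported is the Mann-Whitney U for the first group.
#'
#' @param a,b Numeric vectors, both non-empty; `NA`s dropped.
#' @param exact_max Largest per-group size for the exact enumeration path.
#' @return A one-row tibble: `statistic_name` (`"rank_sum_U"`), `estimate`,
#'   `p_value`, `n_used`, plus a `method` column (`"exact"` or
#'   `"normal_approx"`).
#' @examples
#' rank_sum_test(c(1, 2), c(3, 4))  # exact p = 1/3
#' @export
rank_sum_test <- function(a, b, exact_max = 10L) {
  a <- a[!is.na(a)]
  b <- b[!is.na(b)]
  na <- length(a)
  nb <- length(b)
  if (na == 0L || nb == 0L) abort("Both groups must be non-empty.")
  pooled <- c(a, b)
  n <- na + nb
  r <- rank(pooled)
  ties <- any(duplicated(pooled))
  u <- sum(r[seq_len(na)]) - na * (na + 1) / 2

  if (all(pooled == pooled[1])) {
    warn("All values identical across both groups; p-value set to 1.")
    return(dplyr::mutate(assoc_result("rank_sum_U", u, 1, n),
                         method = "degenerate"))
  }

  if (!ties && na <= exact_max && nb <= exact_max) {
    combos <- utils::combn(n, na)
    rank_sums <- colSums(matrix(seq_len(n)[combos], nrow = na))
    u_all <- rank_sums - na * (na + 1) / 2
    p <- min(1, 2 * min(mean(u_all <= u), mean(u_all >= u)))
    return(dplyr::mutate(assoc_result("rank_sum_U", u, p, n),
                         method = "exact"))
  }

  mu <- na * nb / 2
  tie_tab <- table(pooled)
  tie_term <- sum(tie_tab^3 - tie_tab) / (n * (n - 1))
  sigma2 <- na * nb / 12 * ((n + 1) - tie_term)
  z <- (u - mu - sign(u - mu) * 0.5) / sqrt(sigma2)
  p <- min(1, 2 * pnorm(-abs(z)))
  dplyr::mutate(assoc_result("rank_sum_U", u, p, n), method = "normal_approx")
}

#' Simple linear regression with F test
#'
#' Least-squares fit of `y` on `x`, reporting the slope, intercept, the
#' squared Pearson correlation as R-squared, and the model F statistic
#' `F = (n - 2) R^2 / (1 - R^2)` on (1, n - 2) degrees of freedom with its
#' p-value.
#'
#' @inheritParams assoc_spearman
#' @return A one-row tibble: `slope`, `intercept`, `r_squared`,
#'   `f_statistic`, `df_num`, `df_den`, `p_value`, `n_used`.
#' @export
simple_ols <- function(x, y) {
  d <- drop_incomplete_pairs(x, y)
  n <- length(d$x)
  if (n < 3L) abort("Simple regression needs at least 3 complete pairs.")
  if (stats::var(d$x) == 0) abort("Regression is degenerate: `x` has zero variance.")
  slope <- stats::cov(d$x, d$y) / stats::var(d$x)
  intercept <- mean(d$y) - slope * mean(d$x)
  r2 <- if (stats::var(d$y) == 0) 0 else stats::cor(d$x, d$y)^2
  f <- if (r2 >= 1) Inf else (n - 2) * r2 / (1 - r2)
  tibble(
    slope = slope,
    intercept = intercept,
    r_squared = r2,
    f_statistic = f,
    df_num = 1L,
    df_den = n - 2L,
    p_value = pf(f, 1, n - 2, lower.tail = FALSE),
    n_used = as.integer(n)
  )
}

#' Standardize against reference moments
#'
#' @param value Numeric (vectorized).
#' @param ref_mean,ref_sd Reference mean and SD; `ref_sd` must be positive.
#' @return `(value - ref_mean) / ref_sd`.
#' @export
zscore <- function(value, ref_mean, ref_sd) {
  assert_scalar_number(ref_sd, "ref_sd", 0, strict_lower = TRUE)
  (value - ref_mean) / ref_sd
}
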