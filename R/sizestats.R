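#' Sample skewness
#'
#' Moment-based sample skewness \eqn{g_1 = m_3 / m_2^{3/2}} with central
#' moments \eqn{m_k = n^{-1} \sum (x_i - \bar x)^k} (the b1-type estimator
#' of Joanes & Gill).
#'
#' @param xs numeric vector, `n >= 3`, nonzero variance.
#' @return skewness `g1`.
#' @export
sample_skewness <- function(xs) {
  xs <- as.numeric(xs)
  n <- length(xs)
  if (n < 3) stop("skewness needs at least 3 observations")
  m <- xs - mean(xs)
  m2 <- mean(m^2)
  if (m2 == 0) stop("skewness undefined: zero variance")
  mean(m^3) / m2^1.5
}

#' Excess sample kurtosis
#'
#' Moment-based excess kurtosis \eqn{g_2 = m_4 / m_2^2 - 3}; zero for the
#' normal distribution. Used to check the normality assumption behind the
#' t-tests on volume.
#'
#' @param xs numeric vector, `n >= 4`, nonzero variance.
#' @return excess kurtosis `g2`.
#' @export
excess_kurtosis <- function(xs) {
  xs <- as.numeric(xs)
  n <- length(xs)
  if (n < 4) stop("kurtosis needs at least 4 observations")
  m <- xs - mean(xs)
  m2 <- mean(m^2)
  if (m2 == 0) stop("kurtosis undefined: zero variance")
  mean(m^4) / m2^2 - 3
}

#' Balanced subsampled Bonferroni t-test
#'
#' Compares a strain against its control when the two groups have unequal
#' sizes: in each of `n_iter` iterations the larger (pooled) group is
#' subsampled without replacement to the smaller group's size and a
#' two-sided, equal-variance Student's t-test is run. The median of the
#' `n_iter` p-values is Bonferroni-multiplied by `n_comparisons`; adjusted
#' values above 1 are set to 1.
#'
#' @param control_values control measurements: numeric vector, or a list of
#'   per-replicate vectors (pooled; balancing is on total counts).
#' @param strain_values strain measurements, same forms.
#' @param n_iter number of subsampling iterations (>= 1).
#' @param n_comparisons Bonferroni multiplier.
#' @param seed RNG seed (required; the subsample stream is private and the
#'   global RNG state is untouched).
#' @return list with `p_adjusted`, `p_median` (pre-correction), `p_values`
#'   (all iterations), `n_balanced`.
#' @export
balanced_subsample_ttest <- function(control_values, strain_values,
                                     n_iter = 1000L, n_comparisons = 1L,
                                     seed) {
  if (missing(seed)) stop("seed is required")
  ctl <- unlist(control_values, use.names = FALSE)
  str <- unlist(strain_values, use.names = FALSE)
  if (length(ctl) < 2 || length(str) < 2) {
    stop("both groups need at least 2 values")
  }
  stopifnot(n_iter >= 1)
  n_bal <- min(length(ctl), length(str))
  ps <- with_preserved_rng(seed, {
    vapply(seq_len(n_iter), function(i) {
      a <- if (length(ctl) > n_bal) sample(ctl, n_bal) else ctl
      b <- if (length(str) > n_bal) sample(str, n_bal) else str
      stats::t.test(a, b, var.equal = TRUE)$p.value
    }, numeric(1))
  })
  p_med <- stats::median(ps)
  list(
    p_adjusted = min(1, p_med * n_comparisons),
    p_median = p_med,
    p_values = ps,
    n_balanced = n_bal
  )
}

#' Test for a difference between two regression slopes
#'
#' Fits ordinary least-squares lines to both datasets (width on length in
#' the shape analysis) and tests the slope difference with a Student's t
#' statistic weighted by the standard error of the difference (Zar's
#' procedure): the residual mean square is pooled over both regressions,
#' \deqn{SE_{diff} = \sqrt{s_p^2 / \sum (x_1 - \bar x_1)^2 +
#'                         s_p^2 / \sum (x_2 - \bar x_2)^2},}
#' and \eqn{t = (b_1 - b_2) / SE_{diff}} is referred to the t distribution
#' with `n1 + n2 - 4` degrees of freedom (two-sided).
#'
#' @param x1,y1 first dataset (n >= 3, nonconstant x).
#' @param x2,y2 second dataset.
#' @return list with `b1`, `b2`, `se_diff`, `t_stat`, `df`, `p`. When both
#'   fits are exact (`se_diff == 0`) and the slopes differ, `p` is reported
#'   as the smallest positive double.
#' @export
compare_slopes <- function(x1, y1, x2, y2) {
  fit_one <- function(x, y) {
    if (length(x) < 3) stop("each dataset needs n >= 3")
    if (stats::sd(x) == 0) stop("constant x: slope undefined")
    fit <- stats::lm(y ~ x)
    list(
      b = unname(stats::coef(fit)[2]),
      sse = sum(stats::residuals(fit)^2),
      sxx = sum((x - mean(x))^2),
      n = length(x)
    )
  }
  f1 <- fit_one(x1, y1)
  f2 <- fit_one(x2, y2)
  df <- f1$n + f2$n - 4
  s2p <- (f1$sse + f2$sse) / df
  se_diff <- sqrt(s2p / f1$sxx + s2p / f2$sxx)
  # exact fits leave only floating-point residue; treat as degenerate
  if (se_diff <= sqrt(.Machine$double.eps) * max(abs(f1$b), abs(f2$b), 1e-12)) {
    se_diff <- 0
  }
  if (se_diff == 0) {
    diff0 <- f1$b == f2$b
    return(list(
      b1 = f1$b, b2 = f2$b, se_diff = 0,
      t_stat = if (diff0) 0 else sign(f1$b - f2$b) * Inf,
      df = df,
      p = if (diff0) 1 else .Machine$double.xmin
    ))
  }
  t_stat <- (f1$b - f2$b) / se_diff
  list(
    b1 = f1$b, b2 = f2$b, se_diff = se_diff, t_stat = t_stat, df = df,
    p = 2 * stats::pt(-abs(t_stat), df)
  )
}

#' Per-group sample size from a noncentral-t power analysis
#'
#' Solves for the per-group sample size `n` of a two-sample, two-sided
#' t-test achieving power `1 - beta` at significance `alpha`:
#' \deqn{1 - \beta = 1 - F_{nct}\big(t_{1-\alpha/2,\,df};\; df,\;
#'       ncp = \tfrac{\delta}{\sigma}\sqrt{n/2}\big), \quad df = 2(n-1),}
#' by bisection root-finding on real `n` in \[2, 1e7\] to a tolerance of
#' 1e-6. `delta` and `sigma` are on a common scale (e.g. both as fractions
#' of the control mean, with `sigma` the population CV).
#'
#' @param delta absolute mean difference to detect.
#' @param sigma standard deviation.
#' @param alpha Type I error bound.
#' @param beta Type II error bound (power is `1 - beta`).
#' @return list with `n` (real solution), `n_ceiling`, `df`, `ncp` (at the
#'   real solution) and `achieved_power` at `n_ceiling`.
#' @export
power_sample_size <- function(delta, sigma, alpha = 0.01, beta = 0.2) {
  stopifnot(delta > 0, sigma > 0, alpha > 0, alpha < 1, beta > 0, beta < 1)
  effect <- delta / sigma
  power_at <- function(n) {
    df <- 2 * (n - 1)
    ncp <- effect * sqrt(n / 2)
    1 - stats::pt(stats::qt(1 - alpha / 2, df), df = df, ncp = ncp)
  }
  target <- function(n) power_at(n) - (1 - beta)
  lo <- 2
  hi <- 1e7
  if (target(hi) < 0) stop("infeasible power specification: no n in [2, 1e7]")
  if (target(lo) >= 0) {
    n <- 2
  } else {
    n <- stats::uniroot(target, c(lo, hi), tol = 1e-6)$root
  }
  n_ceil <- ceiling(n - 1e-9)
  list(
    n = n,
    n_ceiling = n_ceil,
    df = 2 * (n - 1),
    ncp = effect * sqrt(n / 2),
    achieved_power = power_at(n_ceil)
  )
}
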