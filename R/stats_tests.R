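# Omnibus normality and paired signed-rank tests used by the precision
# comparison. Both follow the standard large-sample formulations.

#' D'Agostino and Pearson's K^2 test for normality
#'
#' Combines the transformed sample skewness (D'Agostino 1970) and kurtosis
#' (Anscombe and Glynn 1983) statistics into `K^2 = Z_skew^2 + Z_kurt^2`,
#' compared against a chi-squared distribution with 2 degrees of freedom.
#'
#' @param x numeric vector; at least 8 observations (a warning is raised
#'   below 20, where the chi-squared approximation is rough).
#' @return List with `statistic` (K^2), `p_value`, `z_skew`, `z_kurt`, `n`.
#' @export
dagostino_pearson <- function(x) {
  x <- x[is.finite(x)]
  n <- length(x)
  if (n < 8L) stop("D'Agostino-Pearson test requires at least 8 observations")
  if (n < 20L)
    warning("kurtosis test is approximate for n < 20")
  m <- mean(x)
  m2 <- mean((x - m)^2)
  if (m2 == 0) stop("zero variance sample")
  g1 <- mean((x - m)^3) / m2^1.5
  b2 <- mean((x - m)^4) / m2^2

  # skewness: D'Agostino's transformation to approximate normality
  y <- g1 * sqrt((n + 1) * (n + 3) / (6 * (n - 2)))
  beta2 <- 3 * (n^2 + 27 * n - 70) * (n + 1) * (n + 3) /
    ((n - 2) * (n + 5) * (n + 7) * (n + 9))
  w2 <- -1 + sqrt(2 * (beta2 - 1))
  delta <- 1 / sqrt(0.5 * log(w2))
  alpha <- sqrt(2 / (w2 - 1))
  if (y == 0) y <- 1
  z1 <- delta * log(y / alpha + sqrt((y / alpha)^2 + 1))

  # kurtosis: Anscombe-Glynn transformation
  e_b2 <- 3 * (n - 1) / (n + 1)
  var_b2 <- 24 * n * (n - 2) * (n - 3) / ((n + 1)^2 * (n + 3) * (n + 5))
  xs <- (b2 - e_b2) / sqrt(var_b2)
  sqrt_beta1 <- 6 * (n^2 - 5 * n + 2) / ((n + 7) * (n + 9)) *
    sqrt(6 * (n + 3) * (n + 5) / (n * (n - 2) * (n - 3)))
  a <- 6 + 8 / sqrt_beta1 * (2 / sqrt_beta1 + sqrt(1 + 4 / sqrt_beta1^2))
  term1 <- 1 - 2 / (9 * a)
  denom <- 1 + xs * sqrt(2 / (a - 4))
  term2 <- sign(denom) * abs((1 - 2 / a) / abs(denom))^(1 / 3)
  z2 <- (term1 - term2) / sqrt(2 / (9 * a))

  k2 <- z1^2 + z2^2
  list(statistic = k2, p_value = pchisq(k2, df = 2, lower.tail = FALSE),
       z_skew = z1, z_kurt = z2, n = n)
}

#' Wilcoxon signed-rank test with Pratt zero handling
#'
#' Paired two-sided signed-rank test where zero differences are included in
#' the ranking of absolute differences and then discarded (Pratt's method),
#' with the matching adjustments to the null mean and variance; ties among
#' nonzero differences receive average ranks with the usual variance
#' correction. The normal approximation is used throughout.
#'
#' @param x,y paired numeric vectors.
#' @param zero_method `"pratt"` (include zeros in the ranking) or
#'   `"wilcox"` (drop zeros before ranking).
#' @param correction apply a 0.5 continuity correction.
#' @return List with `statistic` (sum of positive ranks), `p_value`, `z`,
#'   `n` (pairs used for ranking) and `n_zero`.
#' @export
wilcoxon_signed_rank <- function(x, y, zero_method = c("pratt", "wilcox"),
                                 correction = FALSE) {
  zero_method <- match.arg(zero_method)
  if (length(x) != length(y)) stop("length mismatch")
  d <- x - y
  d <- d[is.finite(d)]
  if (zero_method == "wilcox") d <- d[d != 0]
  n <- length(d)
  n_zero <- sum(d == 0)
  if (n == 0L || n == n_zero)
    return(list(statistic = 0, p_value = 1, z = 0, n = n, n_zero = n_zero))
  r <- rank(abs(d))
  w_plus <- sum(r[d > 0])
  mu <- (n * (n + 1) / 2 - n_zero * (n_zero + 1) / 2) / 2
  sigma2 <- (n * (n + 1) * (2 * n + 1) -
             n_zero * (n_zero + 1) * (2 * n_zero + 1)) / 24
  ties <- table(abs(d[d != 0]))
  sigma2 <- sigma2 - sum(ties^3 - ties) / 48
  if (sigma2 <= 0)
    return(list(statistic = w_plus, p_value = 1, z = 0, n = n,
                n_zero = n_zero))
  dev <- w_plus - mu
  if (correction) dev <- sign(dev) * max(0, abs(dev) - 0.5)
  z <- dev / sqrt(sigma2)
  list(statistic = w_plus, p_value = 2 * pnorm(-abs(z)), z = z, n = n,
       n_zero = n_zero)
}
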