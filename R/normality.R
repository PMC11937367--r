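#' D'Agostino-Pearson omnibus normality test
#'
#' Combines the skewness transform of D'Agostino (1970) and the kurtosis
#' transform of Anscombe & Glynn (1983) into the K2 statistic, referred
#' to a chi-squared distribution with 2 degrees of freedom. Requires
#' n >= 8 for the kurtosis approximation to be defined.
#'
#' @param x numeric sample, length >= 8.
#' @return list with `statistic` (K2), `p_value`, `z_skewness`,
#'   `z_kurtosis`.
#' @export
dagostino_pearson <- function(x) {
  x <- x[!is.na(x)]
  n <- length(x)
  if (n < 8) stop_input("D'Agostino-Pearson test requires n >= 8")
  m <- mean(x)
  m2 <- mean((x - m)^2); m3 <- mean((x - m)^3); m4 <- mean((x - m)^4)
  g1 <- m3 / m2^1.5
  g2 <- m4 / m2^2 - 3

  # skewness: D'Agostino's Z(g1)
  Y <- g1 * sqrt((n + 1) * (n + 3) / (6 * (n - 2)))
  beta2 <- 3 * (n^2 + 27 * n - 70) * (n + 1) * (n + 3) /
    ((n - 2) * (n + 5) * (n + 7) * (n + 9))
  W2 <- -1 + sqrt(2 * (beta2 - 1))
  delta <- 1 / sqrt(log(sqrt(W2)))
  alpha <- sqrt(2 / (W2 - 1))
  z1 <- delta * log(Y / alpha + sqrt((Y / alpha)^2 + 1))

  # kurtosis: Anscombe-Glynn Z(g2)
  Eg2 <- -6 / (n + 1)
  Vg2 <- 24 * n * (n - 2) * (n - 3) / ((n + 1)^2 * (n + 3) * (n + 5))
  xk <- (g2 - Eg2) / sqrt(Vg2)
  sqrtb1 <- 6 * (n^2 - 5 * n + 2) / ((n + 7) * (n + 9)) *
    sqrt(6 * (n + 3) * (n + 5) / (n * (n - 2) * (n - 3)))
  A <- 6 + 8 / sqrtb1 * (2 / sqrtb1 + sqrt(1 + 4 / sqrtb1^2))
  z2 <- ((1 - 2 / (9 * A)) -
           ((1 - 2 / A) / (1 + xk * sqrt(2 / (A - 4))))^(1 / 3)) /
    sqrt(2 / (9 * A))

  k2 <- z1^2 + z2^2
  list(statistic = k2, p_value = pchisq(k2, df = 2, lower.tail = FALSE),
       z_skewness = z1, z_kurtosis = z2)
}

#' Four-test normality battery with the 3-of-4 parametric rule
#'
#' Runs the four normality tests of the analysis protocol --
#' D'Agostino-Pearson, Anderson-Darling, Shapiro-Wilk and
#' Kolmogorov-Smirnov (Lilliefors-corrected, as in common GUI stats
#' packages) -- at the given alpha. The data are treated as parametric
#' when at least three of the four tests fail to reject normality.
#'
#' @param x numeric sample; n >= 8 required (the D'Agostino-Pearson
#'   minimum). Smaller samples are an error instructing a nonparametric
#'   fallback.
#' @param alpha per-test significance level (default 0.05).
#' @return list with `verdicts` (data.frame test/statistic/p_value/normal)
#'   and `parametric` (logical).
#' @export
normality_battery <- function(x, alpha = 0.05) {
  x <- x[!is.na(x)]
  if (length(x) < 8)
    stop_input("normality battery requires n >= 8; use a nonparametric test for smaller samples")
  dp <- dagostino_pearson(x)
  ad <- nortest::ad.test(x)
  sw <- shapiro.test(x)
  ks <- nortest::lillie.test(x)
  verdicts <- data.frame(
    test = c("D'Agostino-Pearson", "Anderson-Darling", "Shapiro-Wilk",
             "Kolmogorov-Smirnov"),
    statistic = c(dp$statistic, unname(ad$statistic), unname(sw$statistic),
                  unname(ks$statistic)),
    p_value = c(dp$p_value, ad$p.value, sw$p.value, ks$p.value),
    stringsAsFactors = FALSE)
  verdicts$normal <- verdicts$p_value > alpha
  list(verdicts = verdicts, parametric = sum(verdicts$normal) >= 3L)
}
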