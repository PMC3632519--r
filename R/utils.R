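# shared internal helpers

Z95 <- 1.959964

expit <- function(x) 1 / (1 + exp(-x))

#' Round half away from zero
#'
#' Report-layer rounding used for all printed odds ratios and synergy indices:
#' ties are rounded away from zero (so 0.15 -> 0.2, -0.15 -> -0.2), unlike
#' [base::round()]'s round-half-even. Full-precision values are never rounded
#' before being used in downstream computation.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places (default 1).
#' @return Rounded numeric vector.
#' @export
#' @examples
#' round_half_away(c(2.35, -2.35, 0.25), 1)
round_half_away <- function(x, digits = 1) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# draw from a log-normal parameterised by its median and interquartile range,
# truncated to [lo, hi] by inverse-CDF sampling
rlnorm_med_iqr <- function(n, median, iqr, lo = 0, hi = Inf) {
  mu <- log(median)
  sdlog <- log(iqr[2] / iqr[1]) / (2 * stats::qnorm(0.75))
  plo <- stats::plnorm(lo, mu, sdlog)
  phi <- stats::plnorm(hi, mu, sdlog)
  u <- stats::runif(n, plo, phi)
  stats::qlnorm(u, mu, sdlog)
}

# truncated normal via inverse CDF
rnorm_trunc <- function(n, mean, sd, lo = -Inf, hi = Inf) {
  plo <- stats::pnorm(lo, mean, sd)
  phi <- stats::pnorm(hi, mean, sd)
  u <- stats::runif(n, plo, phi)
  stats::qnorm(u, mean, sd)
}
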