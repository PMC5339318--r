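#' @keywords internal
"_PACKAGE"

## Small shared helpers. Nothing here is exported.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Standard error of the mean
#' @noRd
se_mean <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) < 2L) return(NA_real_)
  stats::sd(x) / sqrt(length(x))
}

#' Truncated-normal draws by inverse-CDF (deterministic given the RNG stream,
#' no rejection loop so the stream advances by exactly n uniforms).
#' @noRd
rtruncnorm <- function(n, mean, sd, lower = -Inf, upper = Inf) {
  stopifnot(all(lower < upper))
  if (all(sd == 0)) return(pmin(pmax(rep_len(mean, n), lower), upper))
  p_lo <- stats::pnorm(lower, mean, sd)
  p_hi <- stats::pnorm(upper, mean, sd)
  u <- stats::runif(n)
  q <- stats::qnorm(p_lo + u * (p_hi - p_lo), mean, sd)
  # guard against qnorm(1-eps) overshoot in extreme truncation
  pmin(pmax(q, lower), upper)
}

#' Wilson score interval for a binomial proportion
#' @param x number of successes
#' @param n number of trials
#' @param conf confidence level
#' @return c(estimate, lower, upper)
#' @noRd
wilson_ci <- function(x, n, conf = 0.95) {
  stopifnot(n >= 1L, x >= 0L, x <= n)
  z <- stats::qnorm(1 - (1 - conf) / 2)
  p <- x / n
  denom <- 1 + z^2 / n
  centre <- (p + z^2 / (2 * n)) / denom
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / denom
  c(estimate = p, lower = max(0, centre - half), upper = min(1, centre + half))
}

#' Derive a child seed from a master seed, keeping within 32-bit range.
#' @noRd
child_seed <- function(seed, k) {
  (as.integer(seed) %% 1000003L) * 1009L + as.integer(k)
}
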