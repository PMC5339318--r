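# Independent oracles used across tests. These deliberately avoid the code
# paths they check.

# Upper-tail chi-squared probability via the regularised incomplete gamma
# function, computed by series (x < a + 1) or continued fraction (x >= a + 1),
# following the classic Numerical Recipes decomposition.
chisq_upper_oracle <- function(chi2, df) {
  a <- df / 2; x <- chi2 / 2
  if (x <= 0) return(1)
  if (x < a + 1) {
    # series for the lower regularised gamma P(a, x)
    term <- 1 / a; sum <- term; n <- 0
    while (abs(term) > abs(sum) * 1e-16 && n < 10000) {
      n <- n + 1
      term <- term * x / (a + n)
      sum <- sum + term
    }
    p_lower <- sum * exp(-x + a * log(x) - lgamma(a))
    1 - p_lower
  } else {
    # Lentz continued fraction for the upper regularised gamma Q(a, x)
    tiny <- 1e-300
    b <- x + 1 - a; c <- 1 / tiny; d <- 1 / b; h <- d
    for (i in 1:10000) {
      an <- -i * (i - a)
      b <- b + 2
      d <- an * d + b; if (abs(d) < tiny) d <- tiny
      c <- b + an / c; if (abs(c) < tiny) c <- tiny
      d <- 1 / d
      del <- d * c
      h <- h * del
      if (abs(del - 1) < 1e-16) break
    }
    exp(-x + a * log(x) - lgamma(a)) * h
  }
}

# Brute-force ONLS oracle: coarse grid over (alpha, beta) refined twice, with
# an inner golden-section-free foot-point line search per datum.
onls_grid_oracle <- function(u, y, su = 1, sy = 1, span = 4, steps = 41,
                             refinements = 6) {
  foot_val <- function(ui, yi, a, b) {
    g <- function(us) ((ui - us) / su)^2 + ((yi - a - b / us) / sy)^2
    stats::optimize(g, c(1e-6 * max(u), 4 * max(u)), tol = 1e-11)$objective
  }
  S <- function(a, b) sum(mapply(foot_val, u, y, MoreArgs = list(a = a, b = b)))
  ols <- stats::lm(y ~ I(1 / u))
  ctr <- unname(coef(ols))
  wid <- c(span * max(1, abs(ctr[1])), span * max(1, abs(ctr[2])))
  best <- c(ctr, S(ctr[1], ctr[2]))
  for (r in seq_len(refinements)) {
    as <- seq(best[1] - wid[1], best[1] + wid[1], length.out = steps)
    bs <- seq(best[2] - wid[2], best[2] + wid[2], length.out = steps)
    vals <- outer(as, bs, Vectorize(S))
    idx <- arrayInd(which.min(vals), dim(vals))
    best <- c(as[idx[1]], bs[idx[2]], min(vals))
    wid <- wid * 2.5 / steps * 2   # shrink the window around the minimum
  }
  list(alpha = best[1], beta = best[2], rss = best[3])
}

# shorthand generators reused in several files
make_gp <- function(...) {
  args <- list(name = "G.pulex", pref_intercept = 12.06, pref_slope = 0.1)
  do.call(species_params, utils::modifyList(args, list(...)))
}
make_dv <- function(...) {
  args <- list(name = "D.villosus", pref_intercept = 15.73, pref_slope = -0.1,
               ln_rate_intercept = -5.57, activation_energy = 0.83,
               mean_length = 15.89, mean_mass = 0.0682,
               mortality_intercept = -5.5, mortality_slope = 0.14)
  do.call(species_params, utils::modifyList(args, list(...)))
}

# simulate one Arrhenius recovery: per-temperature mean ln rates from a known
# line plus Gaussian noise, refit, return the slope
simulate_arrhenius_slope <- function(intercept, slope, noise_sd = 0.1,
                                     temps = c(5, 8, 10, 12.5, 15.5, 17.5, 20, 22.5)) {
  x <- boltzmann_x(temps)
  ln_rates <- intercept + slope * x + stats::rnorm(length(temps), 0, noise_sd)
  arrhenius_fit(temps, exp(ln_rates))
}
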