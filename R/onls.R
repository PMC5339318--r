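## Coupling thermal preference with shredding performance: +/-1 degC
## temperature zones around each experimental temperature, habitat use and
## per-capita performance per zone, and an orthogonal non-linear least
## squares fit of performance ~ alpha + beta / habitat-use.

#' Assign recorded temperatures to experimental-temperature zones
#'
#' Each experimental temperature owns the zone 1 degC either side of it.
#' Where zones overlap (e.g. 8 and 10 degC both claim 9.0) records go to the
#' nearer centre, ties to the lower; assignment is half-open
#' `[centre - 1, centre + 1)`.
#'
#' @param temps Recorded temperatures (degC).
#' @param centers Experimental temperatures (zone centres, degC).
#' @param halfwidth Zone half-width (degC, default 1).
#' @return Integer index into `centers` per record (`NA` outside all zones).
#' @export
assign_zone <- function(temps, centers, halfwidth = 1) {
  centers <- sort(centers)
  eps <- 1e-9
  vapply(temps, function(t) {
    d <- abs(t - centers)
    cand <- which(d <= halfwidth + eps)
    if (!length(cand)) return(NA_integer_)
    best <- cand[d[cand] <= min(d[cand]) + eps]
    j <- best[1]                     # distance ties resolve to the lower centre
    # upper zone edge is exclusive unless a tie pulled the record downward
    if (length(best) == 1 && t >= centers[j] + halfwidth - eps)
      return(NA_integer_)
    j
  }, integer(1))
}

#' Habitat use and functional performance per temperature zone
#'
#' For one species: habitat use is the mean number of position records per
#' individual falling in each zone, computed from 15 degC-acclimated animals;
#' performance is the mean leaf mass consumed per individual over the whole
#' trial at the corresponding experimental temperature, computed from usable
#' shredding replicates as `consumed / (amphipod_days / trial_days)` so that
#' mortality reduces the divisor rather than inflating the rate.
#'
#' @param traces Position-trace table for the species (all acclimation
#'   groups; only `acclimation_c == acclimation` rows are used).
#' @param efficiencies Efficiency table from [shredding_efficiency()] for the
#'   same species.
#' @param experimental_temps Zone centres (degC).
#' @param acclimation Acclimation temperature defining habitat use
#'   (default 15).
#' @param halfwidth Zone half-width (degC).
#' @param trial_days Trial length (days) used in the per-individual divisor.
#' @return Data frame per zone: `zone_center`, `zone_low`, `zone_high`,
#'   `habitat_use`, `habitat_use_se`, `performance`, `performance_se`,
#'   `occupancy_fraction`, `n_individuals`, `n_replicates`.
#' @export
zone_summaries <- function(traces, efficiencies, experimental_temps,
                           acclimation = 15, halfwidth = 1, trial_days = 3) {
  tr <- traces[traces$acclimation_c == acclimation, ]
  stopifnot(nrow(tr) > 0)
  ids <- unique(tr$individual_id)
  n_ind <- length(ids)
  centers <- sort(experimental_temps)
  zone <- assign_zone(tr$recorded_temp_c, centers, halfwidth)
  # per-individual per-zone counts (zeros included)
  counts <- matrix(0, n_ind, length(centers),
                   dimnames = list(ids, as.character(centers)))
  ok <- !is.na(zone)
  if (any(ok)) {
    tb <- table(factor(tr$individual_id[ok], levels = ids),
                factor(zone[ok], levels = seq_along(centers)))
    counts <- matrix(as.numeric(tb), n_ind, length(centers))
  }
  eff <- efficiencies[!efficiencies$excluded & efficiencies$amphipod_days > 0, ]
  out <- do.call(rbind, lapply(seq_along(centers), function(j) {
    e <- eff[eff$temp_c == centers[j], ]
    per_ind <- e$consumed_mg / (e$amphipod_days / trial_days)
    data.frame(
      zone_center = centers[j],
      zone_low = centers[j] - halfwidth, zone_high = centers[j] + halfwidth,
      habitat_use = mean(counts[, j]),
      habitat_use_se = se_mean(counts[, j]),
      performance = if (nrow(e) > 0) mean(per_ind) else NA_real_,
      performance_se = if (nrow(e) > 1) se_mean(per_ind) else NA_real_,
      occupancy_fraction = sum(counts[, j]) / nrow(tr),
      n_individuals = n_ind, n_replicates = nrow(e),
      stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

# inner foot-point problem: nearest point on the curve y = alpha + beta/u
# to datum (u_i, y_i) under per-axis scaling (su, sy)
onls_foot <- function(u_i, y_i, alpha, beta, su, sy, lo, hi) {
  g <- function(us) ((u_i - us) / su)^2 + ((y_i - alpha - beta / us) / sy)^2
  opt <- stats::optimize(g, c(lo, hi), tol = 1e-10)
  # the datum's own abscissa is always feasible; keep whichever is better
  if (g(max(u_i, lo)) < opt$objective)
    list(u_star = max(u_i, lo), value = g(max(u_i, lo)))
  else
    list(u_star = opt$minimum, value = opt$objective)
}

#' Orthogonal non-linear least squares fit of performance on habitat use
#'
#' Fits `y = alpha + beta / u` minimising the sum of squared orthogonal
#' (both-axis) distances, appropriate because habitat use and performance
#' are both measured with error. Each axis is standardised by its pooled
#' standard error (unit weights if SEs are absent). The foot point of each
#' datum is found by bounded one-dimensional minimisation nested inside a
#' Nelder-Mead search over (alpha, beta), started from the OLS fit of
#' `y ~ 1/u` plus four fixed dispersed starts.
#'
#' A negative beta gives a curve rising to the asymptote alpha as habitat
#' use grows (performance saturating where the animal spends most time); the
#' t test on beta (df = n - 2) asks whether preference explains performance.
#'
#' @param u Habitat use per zone (must be > 0; zones with zero use are
#'   excluded with a warning).
#' @param y Performance per zone.
#' @param su,sy Axis scales: single pooled SEs, per-zone SE vectors (pooled
#'   by root mean square), or NULL for unit weights.
#' @return Object of class `onls_fit`: `alpha`, `beta`, `se_alpha`,
#'   `se_beta`, `t_stat`, `df`, `p`, `foot_points`, `orthogonal_rss`,
#'   `vertical_rss`, `converged`.
#' @export
#' @examples
#' u <- 1:8
#' f <- onls_fit(u, 2 + 3 / u)
#' c(f$alpha, f$beta)  # 2, 3
onls_fit <- function(u, y, su = NULL, sy = NULL) {
  keep <- is.finite(u) & is.finite(y) & u > 0
  if (any(!keep)) {
    warning(sum(!keep), " zone(s) with zero/undefined use or performance excluded")
    u <- u[keep]; y <- y[keep]
  }
  n <- length(u)
  if (n < 3) stop("need at least 3 zones with positive habitat use")
  pool <- function(s) {
    if (is.null(s) || all(is.na(s))) return(1)
    s <- s[is.finite(s)]
    sqrt(mean(s^2))
  }
  su <- pool(su); sy <- pool(sy)
  if (su <= 0 || sy <= 0) stop("axis scales must be positive")
  lo <- max(1e-8, 1e-4 * stats::median(u))
  hi <- 4 * max(u)
  objective <- function(par) {
    s <- 0
    for (i in seq_len(n))
      s <- s + onls_foot(u[i], y[i], par[1], par[2], su, sy, lo, hi)$value
    s
  }
  # OLS-on-(1/u) initialisation plus fixed dispersed starts
  ols <- stats::lm(y ~ I(1 / u))
  p0 <- unname(stats::coef(ols))
  spread <- max(c(1, stats::sd(y), abs(p0)))
  starts <- list(p0,
                 p0 + c(0.5, -0.5) * spread, p0 + c(-0.5, 0.5) * spread,
                 p0 * c(1.5, 1.5) + c(0.01, 0.01),
                 p0 * c(0.5, 0.5) - c(0.01, 0.01))
  best <- NULL
  for (st in starts) {
    opt <- stats::optim(st, objective, method = "Nelder-Mead",
                        control = list(reltol = 1e-14, maxit = 5000))
    if (is.null(best) || opt$value < best$value) best <- opt
  }
  alpha <- best$par[1]; beta <- best$par[2]
  rss <- best$value
  df <- n - 2L
  # curvature-based covariance: S = sum of squared scaled residuals, so
  # Var(theta) ~ 2 * sigma2 * H^-1 with H the Hessian of S
  H <- stats::optimHess(best$par, objective)
  sigma2 <- if (df > 0) rss / df else NA_real_
  covm <- tryCatch(2 * sigma2 * solve(H), error = function(e)
    matrix(NA_real_, 2, 2))
  se_alpha <- sqrt(covm[1, 1]); se_beta <- sqrt(covm[2, 2])
  t_stat <- beta / se_beta
  p <- if (df > 0) 2 * stats::pt(-abs(t_stat), df) else NA_real_
  feet <- t(vapply(seq_len(n), function(i) {
    ft <- onls_foot(u[i], y[i], alpha, beta, su, sy, lo, hi)
    c(u_star = ft$u_star, y_star = alpha + beta / ft$u_star)
  }, numeric(2)))
  vertical <- sum(((y - alpha - beta / u) / sy)^2)
  structure(list(alpha = alpha, beta = beta,
                 se_alpha = se_alpha, se_beta = se_beta,
                 t_stat = t_stat, df = df, p = p,
                 foot_points = feet, orthogonal_rss = rss,
                 vertical_rss = vertical, su = su, sy = sy,
                 converged = best$convergence == 0, n = n),
            class = "onls_fit")
}

#' @export
print.onls_fit <- function(x, ...) {
  cat(sprintf("ONLS fit: performance = %.3f %+.3f / use\n", x$alpha, x$beta))
  cat(sprintf("  beta: t = %.3f, df = %d, p = %.3f; orthogonal RSS = %.4g\n",
              x$t_stat, x$df, x$p, x$orthogonal_rss))
  invisible(x)
}

#' Two-sided significance of the ONLS slope
#'
#' Student-t test of beta with df = n_zones - 2.
#'
#' @param fit An `onls_fit`, or any list with `t_stat` and `df`.
#' @return List with `t` and two-sided `p`.
#' @export
#' @examples
#' onls_significance(list(t_stat = -2.915, df = 6))$p  # 0.027
onls_significance <- function(fit) {
  stopifnot(!is.null(fit$t_stat), !is.null(fit$df))
  if (fit$df < 1) stop("p undefined with df < 1")
  list(t = fit$t_stat, p = 2 * stats::pt(-abs(fit$t_stat), fit$df))
}
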