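## Population-level shredding capacity: mass-specific rate x mean mass x
## survival x population size, its temperature trend, and species ratios.

#' Project population-level shredding capacity across temperature
#'
#' Capacity of a hypothetical population is the exact product
#' `mass_specific_rate * mean_mass * survival * n_population`, where the
#' mass-specific rate over the whole trial comes from an Arrhenius fit,
#' `rate(T) = trial_days * exp(intercept + E_a * x(T))` in g leaf per g body
#' per trial (the fit's intercept is a per-day rate at the reference
#' temperature).
#'
#' @param fit An `arrhenius_fit` on mass-specific per-day rates.
#' @param survival Data frame with `temp_c` and `survival` (fraction alive at
#'   trial end), e.g. from [survival_rate()], or a function of temperature.
#' @param mean_mass Mean body mass (g); defaults in the two-species study are
#'   0.0305 (G. pulex) and 0.0682 (D. villosus).
#' @param temps Temperatures (degC) at which to project.
#' @param n_population Population size (default 100).
#' @param trial_days Days in the projection window (default 3, i.e. 72 h).
#' @return Data frame per temperature: `species`, `temp_c`,
#'   `mass_specific_rate` (g/g/trial), `mean_mass_g`, `survival`,
#'   `n_population`, `capacity_g` (g leaf per trial).
#' @export
project_capacity <- function(fit, survival, mean_mass, temps,
                             n_population = 100, trial_days = 3) {
  surv <- if (is.function(survival)) survival(temps)
  else {
    stopifnot(all(c("temp_c", "survival") %in% names(survival)))
    idx <- match(temps, survival$temp_c)
    if (anyNA(idx)) stop("survival not defined at every projection temperature")
    survival$survival[idx]
  }
  if (any(surv < 0 | surv > 1)) stop("survival outside [0, 1]")
  rate <- trial_days * exp(fit$intercept + fit$slope * boltzmann_x(temps,
                                                                  fit$ref_c %||% 15))
  data.frame(species = fit$species %||% NA_character_, temp_c = temps,
             mass_specific_rate = rate, mean_mass_g = mean_mass,
             survival = surv, n_population = n_population,
             capacity_g = rate * mean_mass * surv * n_population,
             stringsAsFactors = FALSE)
}

#' Pearson trend of shredding capacity with temperature
#'
#' Correlation of projected capacity against temperature over the projection
#' temperatures, with the two-sided p-value from
#' `t = r sqrt(n-2) / sqrt(1-r^2)` on n - 2 df. A constant capacity has an
#' undefined correlation and is reported as r = 0 with `constant = TRUE`.
#'
#' @param projections Data frame from [project_capacity()] (single species).
#' @return List with `r`, `p`, `n`, `constant`.
#' @export
capacity_trend <- function(projections) {
  stopifnot(all(c("temp_c", "capacity_g") %in% names(projections)))
  n <- nrow(projections)
  if (n < 3) stop("need at least 3 temperatures")
  if (stats::sd(projections$capacity_g) <=
      1e-10 * mean(abs(projections$capacity_g)))
    return(list(r = 0, p = NA_real_, n = n, constant = TRUE))
  ct <- stats::cor.test(projections$temp_c, projections$capacity_g,
                        method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = n, constant = FALSE)
}

#' Percent capacity difference between two species at one temperature
#'
#' `100 * (capacity_a - capacity_b) / capacity_b`: how much more (or less)
#' the first species processes than the second.
#'
#' @param projections_a,projections_b Projection tables for the two species.
#' @param temp Temperature (degC) at which to compare.
#' @return Percent difference.
#' @export
#' @examples
#' # capacity_a = 3 * capacity_b -> 200%
species_capacity_ratio <- function(projections_a, projections_b, temp) {
  ca <- projections_a$capacity_g[projections_a$temp_c == temp]
  cb <- projections_b$capacity_g[projections_b$temp_c == temp]
  if (length(ca) != 1 || length(cb) != 1)
    stop("both species must be projected at the requested temperature")
  if (cb == 0) stop("zero reference capacity: ratio undefined")
  100 * (ca - cb) / cb
}
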