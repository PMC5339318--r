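## Metabolic-theory machinery: Boltzmann temperature standardisation,
## Arrhenius regression of ln mean shredding rate, the 0.60-0.70 eV band
## check, and the species ANCOVA.

#' Boltzmann constant in eV per kelvin
#' @export
boltzmann_k <- 8.62e-5

#' Boltzmann-standardised temperature
#'
#' Converts temperature to `1/(k T_ref) - 1/(k T)` with `k` the Boltzmann
#' constant (8.62e-5 eV/K) and T in kelvin. Zero at the reference (15 degC
#' by default) and strictly increasing in temperature, so the slope of
#' ln(rate) on this variable is the activation energy in eV.
#'
#' @param temp_c Temperature(s) in degC.
#' @param ref_c Reference temperature in degC (default 15).
#' @return Standardised temperature(s), 1/eV.
#' @export
#' @examples
#' boltzmann_x(15)    # 0
#' boltzmann_x(5)     # -1.447
boltzmann_x <- function(temp_c, ref_c = 15) {
  if (any(temp_c <= -273.15) || ref_c <= -273.15)
    stop("temperature at or below absolute zero")
  1 / (boltzmann_k * (ref_c + 273.15)) - 1 / (boltzmann_k * (temp_c + 273.15))
}

#' Arrhenius regression of ln mean shredding rate on temperature
#'
#' Ordinary least squares of `ln(mean rate)` on the Boltzmann-standardised
#' temperature, one point per experimental temperature (per-temperature means
#' are taken first, then logged). The slope estimates the activation energy
#' E_a in eV; 95% confidence intervals use the t distribution with n - 2 df.
#' Non-positive mean rates (ln undefined) are dropped with a warning.
#'
#' @param temps_c Experimental temperatures (degC), one per point.
#' @param mean_rates Mean rates at those temperatures (any positive unit;
#'   the slope is invariant to rescaling, the intercept shifts by ln of the
#'   factor).
#' @param species,dataset Labels carried into the result.
#' @param ref_c Reference temperature for the standardisation.
#' @param conf Confidence level for the intervals.
#' @return Object of class `arrhenius_fit`: `intercept`, `intercept_ci`,
#'   `slope` (E_a, eV), `slope_ci`, `r_squared`, `p` (slope test),
#'   `n_points`, `species`, `dataset`, `ref_c`, and the underlying `lm`.
#' @export
#' @examples
#' x <- boltzmann_x(c(5, 8, 10, 12.5, 15.5, 17.5, 20, 22.5))
#' fit <- arrhenius_fit(c(5, 8, 10, 12.5, 15.5, 17.5, 20, 22.5),
#'                      exp(-5.57 + 0.83 * x))
#' fit$slope  # 0.83
arrhenius_fit <- function(temps_c, mean_rates, species = NA_character_,
                          dataset = NA_character_, ref_c = 15, conf = 0.95) {
  stopifnot(length(temps_c) == length(mean_rates))
  bad <- !is.finite(mean_rates) | mean_rates <= 0
  if (any(bad)) {
    warning(sum(bad), " non-positive mean rate(s) dropped (ln undefined)")
    temps_c <- temps_c[!bad]; mean_rates <- mean_rates[!bad]
  }
  n <- length(temps_c)
  if (n < 3) stop("need at least 3 temperatures with positive mean rates")
  x <- boltzmann_x(temps_c, ref_c = ref_c)
  fit <- stats::lm(log(mean_rates) ~ x)
  sm <- summary(fit)
  ci <- stats::confint(fit, level = conf)
  structure(list(
    species = species, dataset = dataset,
    intercept = unname(stats::coef(fit)[1]),
    intercept_ci = unname(ci[1, ]),
    slope = unname(stats::coef(fit)[2]),
    slope_ci = unname(ci[2, ]),
    r_squared = sm$r.squared,
    p = sm$coefficients[2, 4],
    n_points = n, ref_c = ref_c, lm = fit),
    class = "arrhenius_fit")
}

#' @export
print.arrhenius_fit <- function(x, ...) {
  cat(sprintf("Arrhenius fit (%s, %s): E_a = %.2f eV (%.2f, %.2f), ",
              x$species, x$dataset, x$slope, x$slope_ci[1], x$slope_ci[2]))
  cat(sprintf("intercept %.2f (%.2f, %.2f), R2 = %.2f, n = %d\n",
              x$intercept, x$intercept_ci[1], x$intercept_ci[2],
              x$r_squared, x$n_points))
  invisible(x)
}

#' Per-temperature mean rates from an efficiency table
#'
#' Aggregates usable replicates to one mean rate per species x size-class x
#' temperature. With `mass_specific = TRUE` (default) each replicate's rate
#' is converted to g leaf per g body per day before averaging
#' (`efficiency [mg/ad] / 1000 / mean animal mass [g]`); otherwise the raw
#' per-capita efficiency is averaged.
#'
#' @param records Efficiency table from [shredding_efficiency()].
#' @param mass_specific Logical.
#' @return Data frame `species`, `size_class`, `temp_c`, `mean_rate`, `n`.
#' @export
mean_rates_by_temperature <- function(records, mass_specific = TRUE) {
  d <- records[!records$excluded & !is.na(records$efficiency), ]
  rate <- if (mass_specific) d$efficiency / 1000 / d$mean_mass_g
          else d$efficiency
  key <- interaction(d$species, d$size_class, d$temp_c, drop = TRUE)
  out <- do.call(rbind, lapply(split(seq_len(nrow(d)), key), function(i)
    data.frame(species = d$species[i[1]], size_class = d$size_class[i[1]],
               temp_c = d$temp_c[i[1]], mean_rate = mean(rate[i]),
               n = length(i), stringsAsFactors = FALSE)))
  out <- out[order(out$species, out$size_class, out$temp_c), ]
  rownames(out) <- NULL
  out
}

#' Classify an activation energy against the metabolic-theory band
#'
#' Metabolic theory predicts consumer-resource activation energies of about
#' 0.60-0.70 eV. A fit is `"within"` the band if the point estimate falls in
#' it, `"overlapping-CI"` if only the confidence interval intersects it, and
#' `"outside"` otherwise.
#'
#' @param fit An `arrhenius_fit`, or a list with `slope` and `slope_ci`.
#' @param band Numeric length-2 band in eV (default `c(0.60, 0.70)`).
#' @return `"within"`, `"overlapping-CI"`, or `"outside"`.
#' @export
#' @examples
#' mte_band_check(list(slope = 0.83, slope_ci = c(0.56, 1.10)))
mte_band_check <- function(fit, band = c(0.60, 0.70)) {
  stopifnot(length(band) == 2, band[1] < band[2])
  est <- fit$slope; ci <- fit$slope_ci
  if (est >= band[1] && est <= band[2]) return("within")
  if (!is.null(ci) && !anyNA(ci) && ci[1] <= band[2] && ci[2] >= band[1])
    return("overlapping-CI")
  "outside"
}

#' ANCOVA: does the temperature-shredding relationship differ by species?
#'
#' Fits the full species model `ln(rate) ~ species * x` (species-specific
#' intercepts and slopes, 4 parameters for 2 species) and tests it against a
#' nested reduction. The default `"overall"` compares it to the
#' intercept-only model — the overall regression F with df = (3, n - 4) for
#' 2 species x 8 temperatures, i.e. (3, 12). `"common-line"` tests all
#' species-related terms against the single line `ln(rate) ~ x`
#' (df = (2, n - 4)), and `"interaction-only"` tests just the slope contrast
#' against the parallel-lines model (df = (1, n - 4)).
#'
#' @param x Boltzmann-standardised temperatures.
#' @param ln_rates ln mean rates, same points.
#' @param species Species labels.
#' @param ancova_terms Which nested pair to compare.
#' @return List with `f_stat`, `df` (numerator, denominator), `p`,
#'   `compared_terms`.
#' @export
species_ancova <- function(x, ln_rates, species,
                           ancova_terms = c("overall", "common-line",
                                            "interaction-only")) {
  ancova_terms <- match.arg(ancova_terms)
  species <- factor(species)
  stopifnot(nlevels(species) == 2, all(table(species) >= 3))
  d <- data.frame(x = x, y = ln_rates, species = species)
  full <- stats::lm(y ~ species * x, data = d)
  reduced <- switch(ancova_terms,
                    "overall" = stats::lm(y ~ 1, data = d),
                    "common-line" = stats::lm(y ~ x, data = d),
                    "interaction-only" = stats::lm(y ~ species + x, data = d))
  if (any(!is.finite(stats::coef(full)))) stop("singular ANCOVA design")
  cmp <- stats::anova(reduced, full)
  list(f_stat = cmp$F[2],
       df = c(cmp$Df[2], cmp$Res.Df[2]),
       p = cmp$`Pr(>F)`[2],
       compared_terms = ancova_terms)
}
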