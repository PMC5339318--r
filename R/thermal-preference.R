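## Acute-method preferendum estimation and the control uniformity test.

#' Median selected temperature of one individual
#'
#' The acute method scores each individual by the median of its recorded
#' temperatures over the observation period, avoiding pseudoreplication from
#' repeated records of the same animal. Even record counts return the mean of
#' the two central values.
#'
#' @param temps Numeric vector of recorded temperatures (degC) for one
#'   individual, in observation order.
#' @return Median temperature (degC).
#' @export
#' @examples
#' median_selected_temperature(c(10, 12, 14, 30))  # 13
median_selected_temperature <- function(temps) {
  temps <- as.numeric(temps)
  if (length(temps) == 0L || anyNA(temps))
    stop("trace must contain at least one non-missing temperature")
  stats::median(temps)
}

#' Per-individual medians from a position-trace table
#'
#' @param traces Data frame in the `position_traces` schema (see
#'   [generate_position_traces()]).
#' @return Data frame with one row per individual: `individual_id`,
#'   `species`, `sex`, `acclimation_c`, `median_c`.
#' @export
individual_medians <- function(traces) {
  stopifnot(all(c("individual_id", "species", "acclimation_c",
                  "recorded_temp_c") %in% names(traces)))
  sp <- split(traces, traces$individual_id)
  out <- do.call(rbind, lapply(sp, function(d) data.frame(
    individual_id = d$individual_id[1], species = d$species[1],
    sex = if ("sex" %in% names(d)) d$sex[1] else NA_character_,
    acclimation_c = d$acclimation_c[1],
    median_c = median_selected_temperature(d$recorded_temp_c),
    stringsAsFactors = FALSE)))
  rownames(out) <- NULL
  out
}

#' Acute thermal preferenda by species and acclimation group
#'
#' The acute preferendum of a species at an acclimation temperature is the
#' mean of the individual median selected temperatures in that group, with
#' its standard error. Groups of one animal report `NA` (not zero) for the
#' standard error.
#'
#' @param medians Data frame from [individual_medians()] (columns `species`,
#'   `acclimation_c`, `median_c`).
#' @return Data frame with columns `species`, `acclimation_c`, `mean_c`,
#'   `se_c`, `n`.
#' @export
acute_preferenda <- function(medians) {
  stopifnot(all(c("species", "acclimation_c", "median_c") %in% names(medians)))
  key <- interaction(medians$species, medians$acclimation_c, drop = TRUE)
  out <- do.call(rbind, lapply(split(medians, key), function(d) data.frame(
    species = d$species[1], acclimation_c = d$acclimation_c[1],
    mean_c = mean(d$median_c), se_c = se_mean(d$median_c), n = nrow(d),
    stringsAsFactors = FALSE)))
  out <- out[order(out$species, out$acclimation_c), ]
  rownames(out) <- NULL
  out
}

#' Final thermal preferendum by intersection with the line of equality
#'
#' Fits ordinary least squares of acute preferendum means on acclimation
#' temperature, giving the acute preference line `a + b * T_acc`, and
#' intersects it with the 1:1 line (preferred = acclimation): the final
#' preferendum is `a / (1 - b)`. A parametric bootstrap over the joint
#' sampling distribution of (a, b) gives a percentile confidence interval,
#' since the intersection is a non-linear function of correlated estimates.
#'
#' @param acutes Data frame from [acute_preferenda()] for a single species
#'   (columns `acclimation_c`, `mean_c`).
#' @param n_boot Bootstrap draws for the CI (0 disables it).
#' @param conf Confidence level.
#' @param tol Slopes within `tol` of 1 are treated as parallel to the line of
#'   equality (no finite intersection) and raise an error.
#' @return Object of class `final_preferendum`: list with `species`,
#'   `value_c`, `line_intercept`, `line_slope`, `ci_c`.
#' @export
#' @examples
#' ac <- data.frame(species = "G.pulex", acclimation_c = c(5, 15, 20),
#'                  mean_c = 12.06 + 0.1 * c(5, 15, 20))
#' final_preferendum(ac, n_boot = 0)$value_c  # 13.4
final_preferendum <- function(acutes, n_boot = 1000, conf = 0.95,
                              tol = 1e-6) {
  stopifnot(all(c("acclimation_c", "mean_c") %in% names(acutes)))
  if (length(unique(acutes$acclimation_c)) < 2)
    stop("need at least 2 distinct acclimation temperatures")
  fit <- stats::lm(mean_c ~ acclimation_c, data = acutes)
  a <- unname(stats::coef(fit)[1]); b <- unname(stats::coef(fit)[2])
  if (abs(1 - b) < tol)
    stop("acute preference line is parallel to the line of equality; ",
         "final preferendum diverges")
  value <- a / (1 - b)
  ci <- c(NA_real_, NA_real_)
  if (n_boot > 0 && nrow(acutes) > 2) {
    draws <- MASS::mvrnorm(n_boot, mu = stats::coef(fit),
                           Sigma = stats::vcov(fit))
    vals <- draws[, 1] / (1 - draws[, 2])
    vals <- vals[abs(1 - draws[, 2]) > tol]
    alpha <- (1 - conf) / 2
    ci <- unname(stats::quantile(vals, c(alpha, 1 - alpha)))
  }
  structure(list(species = if ("species" %in% names(acutes))
                             acutes$species[1] else NA_character_,
                 value_c = value, line_intercept = a, line_slope = b,
                 ci_c = ci),
            class = "final_preferendum")
}

#' @export
print.final_preferendum <- function(x, ...) {
  cat(sprintf("Final thermal preferendum (%s): %.2f degC\n",
              x$species, x$value_c))
  cat(sprintf("  acute line: pref = %.3f %+.3f * T_acc\n",
              x$line_intercept, x$line_slope))
  if (!anyNA(x$ci_c))
    cat(sprintf("  bootstrap CI: (%.2f, %.2f) degC\n", x$ci_c[1], x$ci_c[2]))
  invisible(x)
}

#' Chi-squared test of spatial uniformity on the control track
#'
#' Classifies control positions into `bin_width`-cm bins (half-open
#' `[lo, hi)`, last bin closed) and tests the counts against a uniform
#' expectation with Pearson's chi-squared, df = bins - 1. Used to confirm
#' that animals show no positional preference when the track is held at a
#' uniform temperature.
#'
#' @param positions_cm Numeric vector of positions in `[0, track_length]`.
#' @param gradient A [gradient_spec()] object.
#' @return Object of class `uniformity_test`: list with `counts`, `chi2`,
#'   `df`, `p`.
#' @export
control_uniformity_test <- function(positions_cm, gradient = gradient_spec()) {
  positions_cm <- as.numeric(positions_cm)
  if (any(positions_cm < 0 | positions_cm > gradient$track_length))
    stop("positions outside [0, track_length]")
  n_bins <- as.integer(round(gradient$track_length / gradient$bin_width))
  edges <- seq(0, gradient$track_length, length.out = n_bins + 1L)
  idx <- findInterval(positions_cm, edges, rightmost.closed = TRUE,
                      left.open = FALSE)
  counts <- tabulate(idx, nbins = n_bins)
  expected <- length(positions_cm) / n_bins
  if (n_bins > 1L && expected < 1)
    warning("expected count per bin < 1; chi-squared approximation is poor")
  chi2 <- if (n_bins == 1L) 0 else sum((counts - expected)^2 / expected)
  df <- n_bins - 1L
  p <- if (df == 0L) 1 else stats::pchisq(chi2, df, lower.tail = FALSE)
  structure(list(counts = counts, chi2 = chi2, df = df, p = p),
            class = "uniformity_test")
}

#' @export
print.uniformity_test <- function(x, ...) {
  cat(sprintf("Spatial uniformity: chi2 = %.2f, df = %d, p = %.3f\n",
              x$chi2, x$df, x$p))
  invisible(x)
}
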