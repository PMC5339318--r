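## Small-sample AIC, Akaike weights, zero-substitution model averaging, and
## the candidate-model comparison for thermal preference.

#' Small-sample corrected Akaike information criterion
#'
#' `AICc = AIC + 2k(k+1)/(n-k-1)` with `AIC = -2 ln L + 2k`. Requires
#' `n > k + 1` for the correction to be defined.
#'
#' @param neg2_loglik `-2 ln L` of the fitted model.
#' @param k_params Number of estimated parameters (including any variance).
#' @param n_obs Number of observations.
#' @return AICc value.
#' @export
#' @examples
#' aicc(100, 2, 10)  # 105.714...
aicc <- function(neg2_loglik, k_params, n_obs) {
  if (n_obs <= k_params + 1)
    stop("AICc undefined: n_obs must exceed k_params + 1")
  neg2_loglik + 2 * k_params + 2 * k_params * (k_params + 1) / (n_obs - k_params - 1)
}

#' Akaike weights and zero-substitution model averaging
#'
#' Ranks candidate models by AICc, retains those with `delta < delta_cutoff`,
#' normalises `exp(-delta/2)` to Akaike weights over the retained set, and
#' averages coefficients across retained models with zero substituted where a
#' model omits a term.
#'
#' @param models Named list; each element a list with `aicc` (numeric) and
#'   `coefficients` (named numeric vector), and optionally `k_params`.
#' @param delta_cutoff Retention threshold on delta-AICc (default 4).
#' @return Object of class `model_comparison`: list with `table` (data frame
#'   `model`, `k_params`, `aicc`, `delta_aicc`, `akaike_weight`, sorted by
#'   AICc; weight `NA` for dropped models) and `averaged_coefficients`.
#' @export
#' @examples
#' m <- list(A = list(aicc = 100.0, coefficients = c(x = 1)),
#'           B = list(aicc = 101.98, coefficients = c(x = 2, y = 3)))
#' akaike_weights_and_average(m)$table
akaike_weights_and_average <- function(models, delta_cutoff = 4) {
  stopifnot(length(models) >= 1)
  aiccs <- vapply(models, function(m) m$aicc, numeric(1))
  ord <- order(aiccs)
  models <- models[ord]; aiccs <- aiccs[ord]
  delta <- aiccs - aiccs[1]
  keep <- delta < delta_cutoff
  w <- rep(NA_real_, length(models))
  rel <- exp(-delta[keep] / 2)
  w[keep] <- rel / sum(rel)
  tab <- data.frame(
    model = names(models),
    k_params = vapply(models, function(m)
      m$k_params %||% length(m$coefficients), numeric(1)),
    aicc = aiccs, delta_aicc = delta, akaike_weight = w,
    stringsAsFactors = FALSE)
  rownames(tab) <- NULL
  all_terms <- unique(unlist(lapply(models[keep],
                                    function(m) names(m$coefficients))))
  avg <- vapply(all_terms, function(term) {
    sum(vapply(which(keep), function(i) {
      b <- models[[i]]$coefficients
      w[i] * (if (term %in% names(b)) b[[term]] else 0)
    }, numeric(1)))
  }, numeric(1))
  structure(list(table = tab, averaged_coefficients = avg,
                 delta_cutoff = delta_cutoff),
            class = "model_comparison")
}

#' @export
print.model_comparison <- function(x, ...) {
  print(transform(x$table,
                  aicc = round(aicc, 2), delta_aicc = round(delta_aicc, 2),
                  akaike_weight = round(akaike_weight, 3)))
  cat("\nModel-averaged coefficients (zero substitution):\n")
  print(round(x$averaged_coefficients, 4))
  invisible(x)
}

# candidate fixed-effects structures for the preference analysis
preference_candidate_set <- function(has_sex, has_size) {
  f <- c("1", "species", "acclimation_c", "species + acclimation_c",
         "species * acclimation_c")
  if (has_sex) f <- c(f, "sex", "species + sex", "acclimation_c + sex",
                      "species + acclimation_c + sex",
                      "species * acclimation_c + sex")
  if (has_size) f <- c(f, "body_size", "species + acclimation_c + body_size",
                       "species * acclimation_c + body_size")
  f
}

#' Compare candidate thermal-preference models by AICc
#'
#' Fits the candidate set of fixed-effects structures for individual median
#' preferenda — species, acclimation temperature (continuous), their
#' interaction, optionally sex and body size, and all nested subsets — by
#' Gaussian least squares, ranks them by AICc, and model-averages the
#' coefficients of the models within `delta_cutoff` of the best. The residual
#' variance counts as an estimated parameter. Track and run identity can be
#' included as fixed blocking factors via `blocking`.
#'
#' @param medians Data frame with columns `median_c`, `species`,
#'   `acclimation_c`, and optionally `sex`, `body_size`, plus any blocking
#'   columns.
#' @param blocking Character vector of blocking-factor column names added to
#'   every candidate model.
#' @param delta_cutoff Retention threshold on delta-AICc.
#' @param transform Optional monotone function applied to `median_c` before
#'   fitting (e.g. to tame heavy-tailed residuals); default identity.
#' @return A `model_comparison` object with extra elements `top_model` (the
#'   fitted `lm`) and `top_coefficients` (estimate/SE/t/p table).
#' @export
fit_preference_models <- function(medians, blocking = character(),
                                  delta_cutoff = 4, transform = identity) {
  stopifnot(all(c("median_c", "species", "acclimation_c") %in% names(medians)))
  if (length(unique(medians$species)) < 2)
    warning("single species: interaction and species terms are rank-deficient")
  d <- medians
  d$median_c <- transform(d$median_c)
  d$species <- factor(d$species)
  has_sex <- "sex" %in% names(d) && length(unique(d$sex)) > 1
  has_size <- "body_size" %in% names(d)
  cand <- preference_candidate_set(has_sex, has_size)
  block <- if (length(blocking))
    paste("+", paste(blocking, collapse = " + ")) else ""
  fits <- list()
  for (fm in cand) {
    f <- stats::as.formula(paste("median_c ~", fm, block))
    fit <- stats::lm(f, data = d)
    k <- length(stats::coef(fit)[!is.na(stats::coef(fit))]) + 1L  # + sigma
    fits[[fm]] <- list(
      aicc = aicc(-2 * as.numeric(stats::logLik(fit)), k, nrow(d)),
      k_params = k,
      coefficients = stats::coef(fit)[!is.na(stats::coef(fit))],
      fit = fit)
  }
  cmp <- akaike_weights_and_average(
    lapply(fits, function(x) x[c("aicc", "k_params", "coefficients")]),
    delta_cutoff = delta_cutoff)
  top_name <- cmp$table$model[1]
  top <- fits[[top_name]]$fit
  sm <- stats::coef(summary(top))
  cmp$top_model <- top
  cmp$top_coefficients <- data.frame(
    parameter = rownames(sm), estimate = sm[, 1], se = sm[, 2],
    t = sm[, 3], p = sm[, 4], row.names = NULL, stringsAsFactors = FALSE)
  cmp
}
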