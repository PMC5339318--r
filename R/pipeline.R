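## Table validation and end-to-end orchestration of the synthetic study.

check_cols <- function(df, cols, name) {
  miss <- setdiff(cols, names(df))
  if (length(miss))
    sprintf("%s: missing column(s) %s", name, paste(miss, collapse = ", "))
  else character()
}

#' Validate a position-trace table
#'
#' Schema and range checks: required columns, numeric temperatures within
#' the gradient range, at least two records per individual. Returns the
#' character vector of row-level error messages (empty when valid); set
#' `stop_on_error = TRUE` to fail fast instead.
#'
#' @param traces Data frame to check.
#' @param gradient A [gradient_spec()].
#' @param stop_on_error Raise an error on the first problem found.
#' @return Character vector of error messages (invisibly when empty).
#' @export
validate_position_traces <- function(traces, gradient = gradient_spec(),
                                     stop_on_error = FALSE) {
  errs <- check_cols(traces, c("individual_id", "species", "acclimation_c",
                               "obs_minute", "recorded_temp_c"),
                     "position_traces")
  if (!length(errs)) {
    bad <- which(!is.finite(traces$recorded_temp_c) |
                 traces$recorded_temp_c < gradient$temp_cold |
                 traces$recorded_temp_c > gradient$temp_hot)
    if (length(bad))
      errs <- c(errs, sprintf(
        "position_traces row %d: recorded_temp_c %.2f outside [%g, %g]",
        utils::head(bad, 10), traces$recorded_temp_c[utils::head(bad, 10)],
        gradient$temp_cold, gradient$temp_hot))
    n_rec <- table(traces$individual_id)
    few <- names(n_rec)[n_rec < 2]
    if (length(few))
      errs <- c(errs, sprintf("position_traces: individual %s has < 2 records",
                              utils::head(few, 10)))
  }
  if (length(errs) && stop_on_error) stop(paste(errs, collapse = "\n"))
  if (length(errs)) errs else invisible(character())
}

#' Validate a shredding-trial table
#'
#' Checks the one-row-per-animal schema: required columns, positive leaf
#' masses with final <= initial + `mass_tol`, `death_day` within
#' `1..trial_days` or `NA`, and animal-free control pots.
#'
#' @param trials Data frame to check.
#' @param trial_days Trial length in days.
#' @param mass_tol Measurement tolerance (mg) allowed on final > initial.
#' @param stop_on_error Raise an error on the first problem found.
#' @return Character vector of error messages (invisibly when empty).
#' @export
validate_shredding_trials <- function(trials, trial_days = 3, mass_tol = 0.5,
                                      stop_on_error = FALSE) {
  errs <- check_cols(trials, c("replicate_id", "species", "temp_c",
                               "size_class", "death_day", "moulted",
                               "is_control", "leaf_mass_initial_mg",
                               "leaf_mass_final_mg"),
                     "shredding_trials")
  if (!length(errs)) {
    bad_mass <- which(!is.finite(trials$leaf_mass_initial_mg) |
                      trials$leaf_mass_initial_mg <= 0 |
                      trials$leaf_mass_final_mg < 0 |
                      trials$leaf_mass_final_mg >
                        trials$leaf_mass_initial_mg + mass_tol)
    if (length(bad_mass))
      errs <- c(errs, sprintf("shredding_trials row %d: invalid leaf masses",
                              utils::head(bad_mass, 10)))
    dd <- trials$death_day
    bad_dd <- which(!is.na(dd) & (dd < 1 | dd > trial_days | dd != round(dd)))
    if (length(bad_dd))
      errs <- c(errs, sprintf(
        "shredding_trials row %d: death_day %s outside 1..%d",
        utils::head(bad_dd, 10), dd[utils::head(bad_dd, 10)], trial_days))
    ctrl_animals <- which(trials$is_control & !is.na(trials$animal_index))
    if (length(ctrl_animals))
      errs <- c(errs, sprintf("shredding_trials row %d: control pot has animals",
                              utils::head(ctrl_animals, 10)))
  }
  if (length(errs) && stop_on_error) stop(paste(errs, collapse = "\n"))
  if (length(errs)) errs else invisible(character())
}

#' Run the full synthetic study end-to-end
#'
#' Generates data for both species, then runs every analysis stage in
#' dependency order: preferendum estimation (medians, acute means, final
#' preferenda, control uniformity, model comparison), shredding analysis
#' (efficiencies, size index, size-match check, two-way ANOVA, survival),
#' Arrhenius regression with the metabolic-theory band check and species
#' ANCOVA, zone coupling with the ONLS fit, and capacity projection.
#' Re-running with the same configuration and seed reproduces the results
#' exactly. When `outdir` is given, every stage's table is written as CSV.
#'
#' @param params_by_species List of [species_params()].
#' @param design A [design_spec()].
#' @param gradient A [gradient_spec()].
#' @param seed Master seed.
#' @param outdir Optional output directory for CSVs.
#' @param n_boot Bootstrap draws for preferendum CIs.
#' @return Named list of stage results (invisible `data` element holds the
#'   generated tables).
#' @export
run_pipeline <- function(params_by_species = default_species_params(),
                         design = design_spec(), gradient = gradient_spec(),
                         seed = 1L, outdir = NULL, n_boot = 1000) {
  data <- write_or_generate(params_by_species, design, gradient, seed, outdir)
  validate_position_traces(data$traces, gradient, stop_on_error = TRUE)
  validate_shredding_trials(data$trials, design$trial_days,
                            stop_on_error = TRUE)

  med <- individual_medians(data$traces)
  acute <- acute_preferenda(med)
  set.seed(child_seed(seed, 99L))
  finals <- lapply(split(acute, acute$species), final_preferendum,
                   n_boot = n_boot)
  uniformity <- lapply(split(data$controls, data$controls$species),
                       function(d) control_uniformity_test(d$position_cm,
                                                           gradient))
  comparison <- fit_preference_models(med)

  eff <- shredding_efficiency(data$trials)
  matched <- data$trials[!data$trials$is_control &
                         data$trials$size_class == "matched", ]
  bsi <- body_size_index(matched$length_mm, matched$wet_mass_g)
  size_check <- size_match_test(bsi$scores, matched$species)
  anova_matched <- two_way_anova(eff[eff$size_class == "matched", ])
  anova_all <- two_way_anova(eff)
  surv <- survival_rate(data$trials)

  rates <- mean_rates_by_temperature(eff, mass_specific = TRUE)
  fits <- list()
  for (sp in unique(rates$species)) {
    m <- rates[rates$species == sp & rates$size_class == "matched", ]
    a <- rates[rates$species == sp, ]
    a <- stats::aggregate(mean_rate ~ temp_c, a, mean)
    fits[[paste0(sp, ".matched")]] <-
      arrhenius_fit(m$temp_c, m$mean_rate, species = sp, dataset = "size-matched")
    fits[[paste0(sp, ".all")]] <-
      arrhenius_fit(a$temp_c, a$mean_rate, species = sp, dataset = "all-data")
  }
  band <- lapply(fits, mte_band_check)
  sp2 <- unique(rates$species)
  anc <- if (length(sp2) == 2) {
    m <- rates[rates$size_class == "matched", ]
    species_ancova(boltzmann_x(m$temp_c), log(m$mean_rate), m$species)
  } else NULL

  zones <- list(); onls <- list()
  for (sp in sp2) {
    z <- zone_summaries(data$traces[data$traces$species == sp, ],
                        eff[eff$species == sp, ],
                        design$experimental_temps,
                        trial_days = design$trial_days)
    zones[[sp]] <- z
    usable <- z[z$habitat_use > 0 & is.finite(z$performance), ]
    onls[[sp]] <- if (nrow(usable) >= 3)
      onls_fit(usable$habitat_use, usable$performance,
               su = usable$habitat_use_se, sy = usable$performance_se)
    else NULL
  }

  proj <- list()
  for (sp in sp2) {
    mass <- params_by_species[[sp]]$mean_mass
    sv <- surv[surv$species == sp, ]
    proj[[sp]] <- project_capacity(fits[[paste0(sp, ".matched")]], sv, mass,
                                   design$experimental_temps,
                                   trial_days = design$trial_days)
  }
  trends <- lapply(proj, capacity_trend)

  res <- list(medians = med, acute = acute, final_preferenda = finals,
              uniformity = uniformity, model_comparison = comparison,
              efficiencies = eff, body_size = bsi, size_match = size_check,
              anova_matched = anova_matched, anova_all = anova_all,
              survival = surv, mean_rates = rates, arrhenius = fits,
              mte_band = band, ancova = anc, zones = zones, onls = onls,
              projections = proj, capacity_trends = trends,
              seed = seed, data = data)
  if (!is.null(outdir)) write_pipeline_csvs(res, outdir)
  res
}

write_or_generate <- function(params_by_species, design, gradient, seed,
                              outdir) {
  if (!is.null(outdir))
    return(write_synthetic_study(params_by_species, design, gradient,
                                 outdir, seed))
  traces <- do.call(rbind, lapply(seq_along(params_by_species), function(i)
    generate_position_traces(params_by_species[[i]], design, gradient,
                             seed = child_seed(seed, 10L + i))))
  controls <- do.call(rbind, lapply(seq_along(params_by_species), function(i) {
    d <- generate_control_traces(gradient = gradient,
                                 seed = child_seed(seed, 20L + i))
    d$species <- params_by_species[[i]]$name
    d
  }))
  trials <- generate_shredding_trials(params_by_species, design,
                                      seed = child_seed(seed, 30L))
  list(traces = traces, controls = controls, trials = trials)
}

write_pipeline_csvs <- function(res, outdir) {
  wr <- function(df, file) utils::write.csv(df, file.path(outdir, file),
                                            row.names = FALSE)
  wr(res$acute, "preferenda.csv")
  wr(res$model_comparison$table, "model_comparison.csv")
  wr(res$model_comparison$top_coefficients, "top_model_coefficients.csv")
  wr(do.call(rbind, lapply(names(res$uniformity), function(sp) data.frame(
    species = sp, chi2 = res$uniformity[[sp]]$chi2,
    df = res$uniformity[[sp]]$df, p = res$uniformity[[sp]]$p))),
    "uniformity.csv")
  wr(res$efficiencies, "efficiencies.csv")
  wr(res$anova_matched$table, "anova_matched.csv")
  wr(res$anova_all$table, "anova_all.csv")
  wr(res$survival, "survival.csv")
  wr(do.call(rbind, lapply(res$arrhenius, function(f) data.frame(
    species = f$species, dataset = f$dataset,
    intercept = f$intercept, intercept_lo = f$intercept_ci[1],
    intercept_hi = f$intercept_ci[2], slope_ev = f$slope,
    slope_lo = f$slope_ci[1], slope_hi = f$slope_ci[2],
    p = f$p, r_squared = f$r_squared))), "arrhenius.csv")
  wr(do.call(rbind, lapply(names(res$zones), function(sp)
    cbind(species = sp, res$zones[[sp]]))), "zones.csv")
  wr(do.call(rbind, res$projections), "projection.csv")
  invisible(NULL)
}
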