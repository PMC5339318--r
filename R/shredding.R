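## Shredding-trial analysis: amphipod-day exposure, per-replicate efficiency,
## PCA body-size index, size-match check, species x temperature ANOVA, and
## survival with Wilson intervals.

#' Amphipod-days of feeding exposure in one replicate
#'
#' Consumption is standardised by amphipod-days: the number of animals alive
#' on each day summed over the trial. Deaths are recorded at 24 h checks, so
#' the day of death is ambiguous; under the default `"partial"` convention an
#' animal found dead at the day-d check was alive for part of day d and
#' contributes d days, under `"none"` it contributes d - 1.
#'
#' @param death_day Integer vector per animal: day of the check at which the
#'   animal was found dead (`NA` if it survived the trial).
#' @param trial_days Trial length in days.
#' @param death_day_counts `"partial"` (default) or `"none"`.
#' @return Total amphipod-days for the replicate.
#' @export
#' @examples
#' amphipod_days(c(NA, NA))   # 6: both survive 3 days
#' amphipod_days(c(1, NA))    # 4: 1 partial day + 3
amphipod_days <- function(death_day, trial_days = 3,
                          death_day_counts = c("partial", "none")) {
  death_day_counts <- match.arg(death_day_counts)
  if (any(!is.na(death_day) & (death_day < 1 | death_day > trial_days)))
    stop("death_day outside 1..trial_days")
  per_animal <- ifelse(is.na(death_day), trial_days,
                       if (death_day_counts == "partial") death_day
                       else death_day - 1)
  sum(per_animal)
}

#' Per-replicate shredding efficiencies from a trial table
#'
#' Computes, for every non-control replicate, consumed leaf mass corrected
#' for background loss, amphipod-days, and shredding efficiency (mg dry leaf
#' per amphipod-day). Replicates containing a moulted animal, or with zero
#' amphipod-days, are excluded with a reason rather than given an undefined
#' efficiency. Measured mass gain (final > initial) is floored at zero
#' consumption and flagged. Background loss defaults to zero because
#' animal-free control pots lose under 2% of initial mass; pass
#' `control_loss_fraction = "empirical"` to subtract the mean per-temperature
#' control loss instead.
#'
#' @param trials Data frame in the `shredding_trials` schema (one row per
#'   animal; see [generate_shredding_trials()]).
#' @param control_loss_fraction 0 (default), a fixed fraction of initial mass,
#'   or `"empirical"`.
#' @param death_day_counts Passed to [amphipod_days()].
#' @param trial_days Trial length in days.
#' @return Data frame with one row per replicate: `replicate_id`, `species`,
#'   `temp_c`, `size_class`, `amphipod_days`, `consumed_mg`, `efficiency`
#'   (mg per amphipod-day), `mean_mass_g`, `excluded`, `reason`,
#'   `floored`.
#' @export
shredding_efficiency <- function(trials, control_loss_fraction = 0,
                                 death_day_counts = c("partial", "none"),
                                 trial_days = 3) {
  death_day_counts <- match.arg(death_day_counts)
  need <- c("replicate_id", "species", "temp_c", "size_class", "death_day",
            "moulted", "is_control", "leaf_mass_initial_mg",
            "leaf_mass_final_mg")
  stopifnot(all(need %in% names(trials)))
  ctrl <- trials[trials$is_control, ]
  loss_by_temp <- NULL
  if (identical(control_loss_fraction, "empirical")) {
    if (nrow(ctrl) == 0) stop("no control pots for empirical correction")
    frac <- (ctrl$leaf_mass_initial_mg - ctrl$leaf_mass_final_mg) /
      ctrl$leaf_mass_initial_mg
    loss_by_temp <- tapply(frac, ctrl$temp_c, mean)
  }
  d <- trials[!trials$is_control, ]
  out <- do.call(rbind, lapply(split(d, d$replicate_id), function(r) {
    ad <- amphipod_days(r$death_day, trial_days = trial_days,
                        death_day_counts = death_day_counts)
    corr <- if (!is.null(loss_by_temp))
      unname(loss_by_temp[as.character(r$temp_c[1])])
    else control_loss_fraction
    raw <- r$leaf_mass_initial_mg[1] - r$leaf_mass_final_mg[1]
    consumed <- raw - corr * r$leaf_mass_initial_mg[1]
    floored <- consumed < 0
    consumed <- max(0, consumed)
    excluded <- FALSE; reason <- NA_character_
    if (any(r$moulted)) { excluded <- TRUE; reason <- "moult" }
    else if (ad == 0) { excluded <- TRUE; reason <- "zero amphipod-days" }
    data.frame(replicate_id = r$replicate_id[1], species = r$species[1],
               temp_c = r$temp_c[1], size_class = r$size_class[1],
               amphipod_days = ad, consumed_mg = consumed,
               efficiency = if (ad > 0) consumed / ad else NA_real_,
               mean_mass_g = mean(r$wet_mass_g),
               excluded = excluded, reason = reason, floored = floored,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' PCA body-size index from length and mass
#'
#' Length and wet mass are correlated measures of the same underlying size;
#' both are standardised to zero mean and unit variance and combined into the
#' first principal component. For two standardised variables the eigenvalues
#' of the correlation matrix are `1 + r` and `1 - r`, so PC1 explains
#' `(1 + r) / 2` of the variance. Loading signs are fixed so both are
#' positive (bigger animal, bigger score).
#'
#' @param length Numeric vector (any length unit; the index is
#'   scale-invariant).
#' @param mass Numeric vector, same animals.
#' @return Object of class `body_size_index`: list with `scores` (zero-mean
#'   PC1 values), `variance_explained`, `loadings`.
#' @export
body_size_index <- function(length, mass) {
  stopifnot(length(length) == length(mass), length(length) >= 3)
  if (stats::sd(length) == 0 || stats::sd(mass) == 0)
    stop("zero variance in length or mass")
  pc <- stats::prcomp(cbind(length = length, mass = mass),
                      center = TRUE, scale. = TRUE)
  load1 <- pc$rotation[, 1]
  sgn <- if (sum(load1) < 0) -1 else 1
  structure(list(scores = unname(sgn * pc$x[, 1]),
                 variance_explained = pc$sdev[1]^2 / sum(pc$sdev^2),
                 loadings = sgn * load1),
            class = "body_size_index")
}

#' One-way ANOVA of PC1 scores to verify size-matching
#'
#' @param scores Numeric vector of body-size-index scores.
#' @param species Factor/character vector of species labels, same animals.
#' @return Object of class `anova_table` with rows (source, df, F, p) and a
#'   `matched` verdict (`p > 0.05`).
#' @export
size_match_test <- function(scores, species) {
  species <- factor(species)
  stopifnot(nlevels(species) >= 2, all(table(species) >= 2))
  fit <- stats::aov(scores ~ species)
  sm <- summary(fit)[[1]]
  tab <- data.frame(source = trimws(rownames(sm)), df = sm$Df,
                    F = sm$`F value`, p = sm$`Pr(>F)`,
                    stringsAsFactors = FALSE)
  structure(list(table = tab, matched = tab$p[1] > 0.05),
            class = "anova_table")
}

#' @export
print.anova_table <- function(x, ...) {
  print(transform(x$table, F = signif(F, 4), p = signif(p, 3)))
  if (!is.null(x$matched))
    cat(sprintf("size-matching %s (alpha = 0.05)\n",
                if (x$matched) "successful" else "FAILED"))
  invisible(x)
}

#' Two-way ANOVA of shredding efficiency on species and temperature
#'
#' Temperature enters as a categorical factor (the 8 treatment levels).
#' On a balanced design Type-I sums of squares are used; the interaction is
#' dropped by stepwise deletion when non-significant (`p > 0.05`) and the
#' main effects re-tested. Designs with empty cells fall back to Type-II
#' sums of squares with a warning.
#'
#' @param records Efficiency table from [shredding_efficiency()] (excluded
#'   rows are dropped automatically), or any data frame with `species`,
#'   `temp_c`, `efficiency`.
#' @param drop_ns_interaction Apply stepwise deletion of a non-significant
#'   interaction (default TRUE).
#' @return An `anova_table` object; element `interaction_dropped` records the
#'   deletion decision and `fits` holds the underlying `lm`/`aov` objects.
#' @export
two_way_anova <- function(records, drop_ns_interaction = TRUE) {
  stopifnot(all(c("species", "temp_c", "efficiency") %in% names(records)))
  if ("excluded" %in% names(records)) records <- records[!records$excluded, ]
  d <- data.frame(efficiency = records$efficiency,
                  species = factor(records$species),
                  temp = factor(records$temp_c))
  cells <- table(d$species, d$temp)
  if (any(cells == 0)) {
    warning("empty species x temperature cells; using Type-II sums of squares")
    fit <- stats::lm(efficiency ~ species * temp, data = d)
    a2 <- car::Anova(fit, type = 2)
    tab <- data.frame(source = trimws(rownames(a2)), df = a2$Df,
                      F = a2$`F value`, p = a2$`Pr(>F)`,
                      stringsAsFactors = FALSE)
    return(structure(list(table = tab, matched = NULL,
                          interaction_dropped = FALSE, fits = list(full = fit)),
                     class = "anova_table"))
  }
  full <- stats::aov(efficiency ~ species * temp, data = d)
  sm <- summary(full)[[1]]
  if (sm$`Sum Sq`[nrow(sm)] <= 1e-12 * sum(sm$`Sum Sq`))
    stop("zero residual sum of squares: F statistics undefined")
  tab <- data.frame(source = trimws(rownames(sm)), df = sm$Df,
                    F = sm$`F value`, p = sm$`Pr(>F)`,
                    stringsAsFactors = FALSE)
  inter_p <- tab$p[tab$source == "species:temp"]
  dropped <- FALSE
  fits <- list(full = full)
  if (drop_ns_interaction && length(inter_p) == 1 && !is.na(inter_p) &&
      inter_p > 0.05) {
    dropped <- TRUE
    add <- stats::aov(efficiency ~ species + temp, data = d)
    sm2 <- summary(add)[[1]]
    main <- data.frame(source = trimws(rownames(sm2)), df = sm2$Df,
                       F = sm2$`F value`, p = sm2$`Pr(>F)`,
                       stringsAsFactors = FALSE)
    # report re-tested main effects plus the (dropped) interaction row
    tab <- rbind(main[main$source != "Residuals", ],
                 tab[tab$source == "species:temp", ],
                 main[main$source == "Residuals", ])
    fits$additive <- add
  }
  rownames(tab) <- NULL
  structure(list(table = tab, matched = NULL, interaction_dropped = dropped,
                 fits = fits),
            class = "anova_table")
}

#' Pairwise Welch t-tests between temperatures (Holm-corrected)
#'
#' A labelled approximation to post-hoc multiple comparison among temperature
#' levels; off by default in the pipeline.
#'
#' @param records Data frame with `temp_c` and `efficiency`.
#' @return Data frame of pairwise comparisons with Holm-adjusted p-values.
#' @export
pairwise_welch <- function(records) {
  if ("excluded" %in% names(records)) records <- records[!records$excluded, ]
  pt <- stats::pairwise.t.test(records$efficiency, factor(records$temp_c),
                               p.adjust.method = "holm", pool.sd = FALSE)
  m <- pt$p.value
  out <- expand.grid(temp_a = rownames(m), temp_b = colnames(m),
                     stringsAsFactors = FALSE)
  out$p_holm <- as.vector(m)
  out[!is.na(out$p_holm), , drop = FALSE]
}

#' Survival proportions at 72 h with Wilson 95% intervals
#'
#' @param trials Trial table (one row per animal).
#' @return Data frame per species x temperature: `n`, `alive`, `survival`,
#'   `ci_lower`, `ci_upper`.
#' @export
survival_rate <- function(trials) {
  d <- trials[!trials$is_control, ]
  stopifnot(nrow(d) > 0)
  key <- interaction(d$species, d$temp_c, drop = TRUE)
  out <- do.call(rbind, lapply(split(d, key), function(r) {
    n <- nrow(r); alive <- sum(is.na(r$death_day))
    ci <- wilson_ci(alive, n)
    data.frame(species = r$species[1], temp_c = r$temp_c[1], n = n,
               alive = alive, survival = ci[["estimate"]],
               ci_lower = ci[["lower"]], ci_upper = ci[["upper"]],
               stringsAsFactors = FALSE)
  }))
  out <- out[order(out$species, out$temp_c), ]
  rownames(out) <- NULL
  out
}
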