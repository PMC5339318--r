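test_that("amphipod-days follow the death-day convention", {
  expect_equal(amphipod_days(c(NA, NA)), 6)
  expect_equal(amphipod_days(c(1, NA)), 4)   # 1 partial day + 3 full
  expect_equal(amphipod_days(c(1, 1)), 2)
  expect_equal(amphipod_days(c(1, NA), death_day_counts = "none"), 3)
  expect_equal(amphipod_days(c(2, 3)), 5)
  expect_error(amphipod_days(c(4, NA)))
  # bounded by animals x days
  expect_lte(amphipod_days(c(3, 3)), 2 * 3)
})

make_trial <- function(initial = 16, final = 10, death = c(NA, NA),
                       moulted = c(FALSE, FALSE), temp = 15.5) {
  data.frame(replicate_id = "r1", species = "G.pulex", temp_c = temp,
             size_class = "matched", animal_index = 1:2,
             length_mm = c(12, 13), wet_mass_g = c(0.03, 0.032),
             death_day = death, moulted = moulted, is_control = FALSE,
             leaf_mass_initial_mg = initial, leaf_mass_final_mg = final)
}

test_that("shredding efficiency standardises consumption by amphipod-days", {
  eff <- shredding_efficiency(make_trial())
  expect_equal(eff$efficiency, 1.0)   # (16 - 10) / 6
  expect_false(eff$excluded)
  # moulted animal disqualifies the replicate
  effm <- shredding_efficiency(make_trial(moulted = c(TRUE, FALSE)))
  expect_true(effm$excluded)
  expect_equal(effm$reason, "moult")
  # zero amphipod-days is an exclusion, not an infinite rate
  eff0 <- shredding_efficiency(make_trial(death = c(1, 1)),
                               death_day_counts = "none")
  expect_true(eff0$excluded)
  expect_true(is.na(eff0$efficiency))
  # apparent mass gain floors at zero with a flag
  effg <- shredding_efficiency(make_trial(final = 16.4))
  expect_equal(effg$consumed_mg, 0)
  expect_true(effg$floored)
  # empirical control correction subtracts the mean per-temperature loss
  ctrl <- data.frame(replicate_id = "c1", species = NA, temp_c = 15.5,
                     size_class = "control", animal_index = NA,
                     length_mm = NA, wet_mass_g = NA, death_day = NA,
                     moulted = FALSE, is_control = TRUE,
                     leaf_mass_initial_mg = 16, leaf_mass_final_mg = 15.84)
  effc <- shredding_efficiency(rbind(make_trial(), ctrl),
                               control_loss_fraction = "empirical")
  expect_equal(effc$consumed_mg, 6 - 0.01 * 16)
})

test_that("efficiency depends only on totals, not their split across days", {
  # same consumed mass with deaths on different days but equal exposure
  a <- shredding_efficiency(make_trial(death = c(2, NA)))  # 2 + 3 = 5 ad
  b <- shredding_efficiency(make_trial(death = c(NA, 2)))
  expect_equal(a$efficiency, b$efficiency)
})

test_that("body-size index: variance explained is (1 + r)/2 and unit-free", {
  set.seed(2)
  n <- 300
  z <- rnorm(n)
  len <- 12 + 1.5 * z
  mass <- 0.03 + 0.01 * (0.8 * z + sqrt(1 - 0.64) * rnorm(n))
  bsi <- body_size_index(len, mass)
  r <- cor(len, mass)
  expect_equal(bsi$variance_explained, (1 + r) / 2, tolerance = 1e-12)
  expect_equal(mean(bsi$scores), 0, tolerance = 1e-12)
  expect_true(all(bsi$loadings > 0))
  # affine unit changes (mm -> cm, g -> mg) leave scores identical
  bsi_cm <- body_size_index(len / 10, mass * 1000)
  expect_equal(bsi$scores, bsi_cm$scores, tolerance = 1e-9)
  # perfectly correlated pair loads everything on PC1
  expect_equal(body_size_index(z + 5, 2 * z + 3)$variance_explained, 1)
  expect_error(body_size_index(rep(1, 5), 1:5), "variance")
})

test_that("size-match ANOVA verdicts behave under null and shifted sizes", {
  # mirrored groups: identical means, F = 0
  sc <- c(-1, 0, 1, -1, 0, 1)
  sp <- rep(c("a", "b"), each = 3)
  sm <- size_match_test(sc, sp)
  expect_equal(sm$table$F[1], 0)
  expect_equal(sm$table$p[1], 1)
  expect_true(sm$matched)
  # null sizes: p roughly uniform (coarse check on 200 sims)
  set.seed(4)
  ps <- replicate(200, size_match_test(rnorm(40), rep(c("a", "b"), 20))$table$p[1])
  expect_gt(ks.test(ps, "punif")$p.value, 0.001)
  # a 2-SD gap with n = 160/group is detected essentially always
  set.seed(5)
  hit <- replicate(50, {
    x <- c(rnorm(160), rnorm(160, 2))
    size_match_test(x, rep(c("a", "b"), each = 160))$table$p[1] < 0.05
  })
  expect_gte(mean(hit), 0.99)
  expect_error(size_match_test(rnorm(5), rep("a", 5)))
})

test_that("two-way ANOVA decomposes balanced sums of squares exactly", {
  set.seed(6)
  d <- expand.grid(species = c("G", "D"), temp_c = c(5, 8, 10, 12.5),
                   rep = 1:6)
  d$efficiency <- rnorm(nrow(d), 1 + (d$species == "G") * 0.5 + d$temp_c / 20)
  res <- two_way_anova(d, drop_ns_interaction = FALSE)
  fit <- res$fits$full
  sm <- summary(fit)[[1]]
  ss <- sm$`Sum Sq`
  total <- sum((d$efficiency - mean(d$efficiency))^2)
  expect_equal(sum(ss), total, tolerance = 1e-8)
  expect_equal(res$table$df[1:3], c(1, 3, 3))
})

test_that("two-way ANOVA drops a non-significant interaction stepwise", {
  # additive truth: species offset plus a common temperature response
  set.seed(21)
  d <- expand.grid(species = c("G", "D"),
                   temp_c = c(5, 8, 10, 12.5, 15.5, 17.5, 20, 22.5), rep = 1:10)
  d$efficiency <- 1 + 0.6 * (d$species == "G") + 0.05 * d$temp_c +
    rnorm(nrow(d), 0, 0.3)
  res <- two_way_anova(d)
  expect_true(res$interaction_dropped)
  expect_equal(res$table$source,
               c("species", "temp", "species:temp", "Residuals"))
  p_species <- res$table$p[res$table$source == "species"]
  expect_lt(p_species, 0.001)
  # zero residual noise makes F undefined: error path
  d0 <- expand.grid(species = c("G", "D"), temp_c = c(5, 8, 10), rep = 1:3)
  d0$efficiency <- 1 + (d0$species == "G") + d0$temp_c
  expect_error(two_way_anova(d0), "residual")
  # empty cell falls back to Type-II with a warning
  dd <- d0[!(d0$species == "G" & d0$temp_c == 5), ]
  dd$efficiency <- dd$efficiency + rnorm(nrow(dd), 0, 0.1)
  expect_warning(two_way_anova(dd), "Type-II")
})

test_that("survival rates and Wilson intervals are correct and ordered", {
  tr <- rbind(make_trial(death = c(NA, NA)),
              transform(make_trial(death = c(1, NA)), replicate_id = "r2"))
  sv <- survival_rate(tr)
  expect_equal(sv$survival, 3 / 4)
  # no deaths: estimate 1 with upper bound 1
  tr2 <- make_trial()
  sv2 <- survival_rate(tr2)
  expect_equal(sv2$survival, 1)
  expect_equal(sv2$ci_upper, 1)
  expect_lt(sv2$ci_lower, 1)
  # 10 of 20 dead: Wilson centre just under half
  w <- wilson <- thermoshred:::wilson_ci(10, 20)
  expect_equal(unname(w["estimate"]), 0.5)
  expect_equal(unname(w["lower"]), 0.299, tolerance = 1e-3)
  expect_equal(unname(w["upper"]), 0.701, tolerance = 1e-3)
  # generator ordering: steeper mortality slope, steeper survival decline
  gp <- make_gp(); dv <- make_dv()
  tr3 <- generate_shredding_trials(list(gp, dv),
                                   design_spec(n_replicates = 30), seed = 3)
  sv3 <- survival_rate(tr3)
  g <- sv3[sv3$species == "G.pulex", ]; d <- sv3[sv3$species == "D.villosus", ]
  expect_lt(cor(g$temp_c, g$survival), 0)
  drop_g <- g$survival[g$temp_c == 5] - g$survival[g$temp_c == 22.5]
  drop_d <- d$survival[d$temp_c == 5] - d$survival[d$temp_c == 22.5]
  expect_gt(drop_g, drop_d)
})
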