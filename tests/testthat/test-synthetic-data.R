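test_that("generators are deterministic under a fixed seed", {
  gp <- make_gp()
  d <- design_spec(n_per_acclimation = 5, n_replicates = 2)
  expect_identical(generate_position_traces(gp, d, seed = 42),
                   generate_position_traces(gp, d, seed = 42))
  expect_identical(generate_body_sizes(gp, 50, seed = 42),
                   generate_body_sizes(gp, 50, seed = 42))
  expect_identical(generate_shredding_trials(list(gp), d, seed = 42),
                   generate_shredding_trials(list(gp), d, seed = 42))
  # and different seeds move the draws
  expect_false(identical(generate_position_traces(gp, d, seed = 42),
                         generate_position_traces(gp, d, seed = 43)))
})

test_that("position traces follow the design and respect the gradient", {
  gp <- make_gp()
  d <- design_spec(n_per_acclimation = 10)
  g <- gradient_spec()
  tr <- generate_position_traces(gp, d, g, seed = 1)
  # 3 acclimation groups x 10 animals x 15 records (intervals ending at 45)
  expect_equal(nrow(tr), 3 * 10 * 15)
  expect_equal(sort(unique(tr$obs_minute)), seq(3, 45, 3))
  expect_true(all(tr$recorded_temp_c >= g$temp_cold &
                  tr$recorded_temp_c <= g$temp_hot))
  # degenerate noise: every record sits exactly on the preference line
  gp0 <- make_gp(pref_sd = 0)
  tr0 <- generate_position_traces(gp0, d, g, seed = 1)
  expect_equal(tr0$recorded_temp_c,
               12.06 + 0.1 * tr0$acclimation_c, tolerance = 1e-12)
  # acclimation temperature outside the gradient is rejected
  expect_error(generate_position_traces(
    gp, design_spec(acclimation_temps = c(5, 30)), g, seed = 1),
    "outside the gradient")
})

test_that("control traces give 180 uniform records per default design", {
  g <- gradient_spec()
  ctrl <- generate_control_traces(6, 30, g, seed = 9)
  expect_equal(nrow(ctrl), 180)
  expect_true(all(ctrl$position_cm >= 0 & ctrl$position_cm < g$track_length))
})

test_that("uniform control positions reject at the nominal 5% rate", {
  g <- gradient_spec()
  reject <- vapply(1:400, function(s) {
    ctrl <- generate_control_traces(6, 30, g, seed = s)
    control_uniformity_test(ctrl$position_cm, g)$p < 0.05
  }, logical(1))
  # binomial(400, .05) 99.9% interval is about (0.02, 0.09)
  expect_gt(mean(reject), 0.015)
  expect_lt(mean(reject), 0.10)
})

test_that("body sizes hit the target moments and correlation structure", {
  gp <- make_gp()
  sz <- generate_body_sizes(gp, 4000, seed = 3)
  expect_equal(mean(sz$length_mm), gp$mean_length, tolerance = 0.02)
  expect_equal(mean(sz$wet_mass_g), gp$mean_mass, tolerance = 0.02)
  expect_equal(sd(sz$length_mm) / mean(sz$length_mm), gp$size_cv,
               tolerance = 0.05)
  expect_equal(cor(log(sz$length_mm), log(sz$wet_mass_g)),
               gp$length_mass_corr, tolerance = 0.02)
  expect_true(all(sz$length_mm > 0 & sz$wet_mass_g > 0))
  # n = 2 gives a degenerate sample correlation of +/-1
  s2 <- generate_body_sizes(gp, 2, seed = 1)
  expect_equal(abs(cor(s2$length_mm, s2$wet_mass_g)), 1)
  expect_error(generate_body_sizes(make_gp(length_mass_corr = 1.2), 10, 1))
})

test_that("shredding trials: immortal animals give full amphipod-day exposure", {
  gp <- make_gp(mortality_intercept = -50, mortality_slope = 0, moult_prob = 0)
  d <- design_spec(n_replicates = 3)
  tr <- generate_shredding_trials(list(gp), d, seed = 5)
  eff <- shredding_efficiency(tr)
  expect_true(all(eff$amphipod_days == d$animals_per_pot * d$trial_days))
  expect_true(all(tr$leaf_mass_final_mg >= 0))
  expect_true(all(tr$leaf_mass_initial_mg > 0))
})

test_that("no temperature dependence and no noise flattens consumption", {
  gp <- make_gp(activation_energy = 0, rate_noise_sd = 0, moult_prob = 0,
                mortality_intercept = -50, mortality_slope = 0,
                size_cv = 1e-6)
  d <- design_spec(n_replicates = 4)
  tr <- generate_shredding_trials(list(gp), d, seed = 5)
  eff <- shredding_efficiency(tr)
  by_temp <- tapply(eff$consumed_mg, eff$temp_c, mean)
  expect_lt(diff(range(by_temp)), 1e-6 * mean(by_temp))
})

test_that("control pots lose under 2% of initial mass by construction", {
  tr <- generate_shredding_trials(list(make_gp()),
                                  design_spec(n_replicates = 2), seed = 11)
  ctrl <- tr[tr$is_control, ]
  loss <- (ctrl$leaf_mass_initial_mg - ctrl$leaf_mass_final_mg) /
    ctrl$leaf_mass_initial_mg
  expect_true(all(loss >= 0 & loss < 0.02))
  expect_true(all(is.na(ctrl$animal_index)))
})

test_that("pipeline recovers the generating activation energy from trials", {
  # moderate replication; the acceptance suite runs the full 200-seed version
  dv <- make_dv(rate_noise_sd = 0.2, moult_prob = 0,
                mortality_intercept = -50, mortality_slope = 0)
  d <- design_spec(n_replicates = 5)
  slopes <- vapply(1:40, function(s) {
    tr <- generate_shredding_trials(list(dv), d, seed = s)
    eff <- shredding_efficiency(tr)
    rates <- mean_rates_by_temperature(eff[eff$size_class == "matched", ])
    arrhenius_fit(rates$temp_c, rates$mean_rate)$slope
  }, numeric(1))
  expect_equal(mean(slopes), 0.83, tolerance = 0.05)
})
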