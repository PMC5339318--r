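test_that("capacity is the exact product identity and linear in its factors", {
  fit <- list(species = "D.villosus", intercept = log(0.1 / 3), slope = 0,
              ref_c = 15)
  surv <- data.frame(temp_c = 15, survival = 0.5)
  pr <- project_capacity(fit, surv, mean_mass = 0.0682, temps = 15)
  expect_equal(pr$capacity_g, 0.1 * 0.0682 * 0.5 * 100, tolerance = 1e-12)
  # identity holds on random inputs
  set.seed(18)
  for (i in 1:10) {
    f <- list(species = "x", intercept = rnorm(1, -5), slope = runif(1, 0, 1),
              ref_c = 15)
    temps <- c(5, 10, 15, 20)
    sv <- data.frame(temp_c = temps, survival = runif(4))
    mm <- runif(1, 0.01, 0.1); np <- sample(10:500, 1)
    p <- project_capacity(f, sv, mm, temps, n_population = np)
    expect_equal(p$capacity_g,
                 p$mass_specific_rate * p$mean_mass_g * p$survival * np,
                 tolerance = 1e-12)
    # linear in population size and mean mass
    p2 <- project_capacity(f, sv, 2 * mm, temps, n_population = 2 * np)
    expect_equal(p2$capacity_g, 4 * p$capacity_g, tolerance = 1e-12)
  }
  expect_error(project_capacity(fit, data.frame(temp_c = 15, survival = 1.2),
                                0.05, 15), "survival")
  expect_error(project_capacity(fit, surv, 0.05, temps = c(15, 20)),
               "every projection temperature")
})

test_that("full survival and positive activation give rising capacity", {
  fit <- list(species = "x", intercept = -5, slope = 0.7, ref_c = 15)
  temps <- c(5, 8, 10, 12.5, 15.5, 17.5, 20, 22.5)
  sv <- data.frame(temp_c = temps, survival = 1)
  p <- project_capacity(fit, sv, 0.05, temps)
  expect_true(all(diff(p$capacity_g) > 0))
  tr <- capacity_trend(p)
  expect_gt(tr$r, 0.95)
})

test_that("log-capacity species contrast matches its closed form", {
  temps <- c(5, 10, 15, 20)
  fg <- list(species = "G", intercept = -4.53, slope = 0.40, ref_c = 15)
  fd <- list(species = "D", intercept = -5.57, slope = 0.83, ref_c = 15)
  sv <- data.frame(temp_c = temps, survival = 1)
  pg <- project_capacity(fg, sv, 0.0305, temps)
  pd <- project_capacity(fd, sv, 0.0682, temps)
  x <- boltzmann_x(temps)
  expected <- (fg$intercept - fd$intercept) + (fg$slope - fd$slope) * x +
    log(0.0305 / 0.0682)
  expect_equal(log(pg$capacity_g) - log(pd$capacity_g), expected,
               tolerance = 1e-10)
})

test_that("mortality tuned to cancel the rate leaves capacity flat", {
  # survival(T) = s0 exp(-E_a x(T)) makes the product exactly constant;
  # s0 keeps survival inside [0, 1] at the coldest temperature
  fit <- list(species = "x", intercept = -3, slope = 0.6, ref_c = 15)
  temps <- c(5, 8, 10, 12.5, 15.5, 17.5, 20, 22.5)
  xs <- boltzmann_x(temps)
  s0 <- exp(0.6 * min(xs))
  sv <- data.frame(temp_c = temps, survival = s0 * exp(-0.6 * xs))
  expect_true(all(sv$survival > 0 & sv$survival <= 1))
  tr <- capacity_trend(project_capacity(fit, sv, 0.03, temps))
  expect_true(tr$constant)
  expect_equal(tr$r, 0)
  # noisy survivals around that curve keep |r| small in most seeds
  set.seed(19)
  rs <- replicate(100, {
    svn <- transform(sv, survival = pmin(1, pmax(0,
      survival * exp(rnorm(8, 0, 0.05)))))
    capacity_trend(project_capacity(fit, svn, 0.03, temps))$r
  })
  expect_gt(mean(abs(rs) < 0.5), 0.6)
})

test_that("capacity trend t-transform reproduces the printed correlation test", {
  # construct 8 points with sample correlation ~0.913 and check p ~ 0.002
  set.seed(20)
  temps <- c(5, 8, 10, 12.5, 15.5, 17.5, 20, 22.5)
  zx <- temps - mean(temps); zx <- zx / sqrt(sum(zx^2))
  e <- resid(lm(rnorm(8) ~ temps)); e <- e / sqrt(sum(e^2))
  r0 <- 0.913
  cap <- r0 * zx + sqrt(1 - r0^2) * e   # sample correlation exactly 0.913
  tr <- capacity_trend(data.frame(temp_c = temps, capacity_g = cap))
  expect_equal(tr$r, 0.913, tolerance = 1e-9)
  expect_equal(tr$p, 0.0015, tolerance = 0.05)
  # constant capacity flagged, not NaN
  flat <- capacity_trend(data.frame(temp_c = temps, capacity_g = rep(1, 8)))
  expect_equal(flat$r, 0)
  expect_true(flat$constant)
})

test_that("species capacity ratio is the percent difference definition", {
  pa <- data.frame(temp_c = c(5, 22.5), capacity_g = c(3, 1.2))
  pb <- data.frame(temp_c = c(5, 22.5), capacity_g = c(1, 1))
  expect_equal(species_capacity_ratio(pa, pb, 5), 200)
  expect_equal(species_capacity_ratio(pa, pb, 22.5), 20)
  expect_equal(species_capacity_ratio(pb, pb, 5), 0)
  expect_error(species_capacity_ratio(pa, transform(pb, capacity_g = 0), 5))
})
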