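test_that("closed-form death time covers boundary, finite and immortal regimes", {
  expect_equal(death_time_closed_form(1, 0, 0.1, 1), 0)      # starts at threshold
  # pure decay: t* = log2(M0/T) x molecular half-life
  d <- log(2) / 14
  expect_equal(death_time_closed_form(6.6, 0, d, 1), log2(6.6) * 14,
               tolerance = 1e-12)
  expect_equal(round(death_time_closed_form(6.6, 0, d, 1), 1), 38.1)
  # steady state exactly at threshold: asymptotic approach, never crosses
  expect_true(is.infinite(death_time_closed_form(2, 0.5, 0.5, 1)))
  # steady state above threshold
  expect_true(is.infinite(death_time_closed_form(2, 2, 1, 1)))
  expect_error(death_time_closed_form(1, 0, -0.1, 0.5), "positive")
})

test_that("dormancy half-life scales as log2(M0/T) times the molecular half-life", {
  for (case in list(c(5, 1), c(6.6, 1), c(10, 2), c(3, 0.4))) {
    M0 <- case[1]; Th <- case[2]
    for (hl in c(4, 8.4, 14)) {
      d <- log(2) / hl
      expect_equal(death_time_closed_form(M0, 0, d, Th) / hl,
                   log2(M0 / Th), tolerance = 1e-12)
    }
  }
})

test_that("homogeneous populations die as a step at the closed-form time", {
  sp <- species_params("m", production_per_day = 0.01,
                       degradation_per_day = 0.1, threshold_frac = 0.3,
                       initial_cv = 0)
  params <- death_model_params(list(sp), n_spores = 50, seed = 1)
  t_star <- death_time_closed_form(1, 0.01, 0.1, 0.3)
  days <- sort(c(seq(0, 30, 2), t_star - 0.01, t_star + 0.01))
  sim <- simulate_population(params, days)
  expect_equal(unique(sim$death_days), t_star, tolerance = 1e-10)
  expect_equal(sim$survival$fraction_alive,
               as.numeric(days < t_star | days == t_star))

  # immortal limit: steady state above threshold
  sp2 <- species_params("m", production_per_day = 0.1,
                        degradation_per_day = 0.1, threshold_frac = 0.3,
                        initial_cv = 0)
  sim2 <- simulate_population(death_model_params(list(sp2), 20, seed = 1),
                              seq(0, 100, 20))
  expect_true(all(sim2$survival$fraction_alive == 1))

  expect_error(death_model_params(list(), 10), "empty")
})

test_that("piecewise-analytic levels agree with numerical integration to 1e-8", {
  skip_if_not_installed("deSolve")
  p <- 0.02; d <- 0.08; scale_in_drug <- 0
  schedule <- list(list(start_day = 10, end_day = 20, condition = "chx",
                        production_scale = c(m = scale_in_drug)))
  sp <- species_params("m", p, d, threshold_frac = 0.05, initial_cv = 0)
  params <- death_model_params(list(sp), n_spores = 1, schedule, seed = 1)
  days <- seq(0, 30, by = 1)
  sim <- simulate_population(params, days)

  rhs <- function(t, y, parms) {
    scale <- if (t >= 10 && t < 20) scale_in_drug else 1
    list(p * scale - d * y)
  }
  ode <- deSolve::ode(c(M = 1), days, rhs, NULL, rtol = 1e-12, atol = 1e-12)
  expect_equal(unname(sim$levels$m[1, ]), unname(ode[, "M"]),
               tolerance = 1e-8)
})

test_that("(p, d) round-trip: cohort half-lives invert to the generative rates", {
  d <- log(2) / 8.4
  p <- d - log(2) / 14
  mk <- function(schedule) {
    sp <- species_params("rnap2", p, d, threshold_frac = 0.01,
                         initial_cv = 0.3, production_model = "first_order")
    death_model_params(list(sp), n_spores = 1000, schedule, seed = 6)
  }
  chx <- list(list(start_day = 0, end_day = Inf, condition = "chx",
                   production_scale = c(rnap2 = 0)))
  days <- seq(0, 20, by = 2)
  mean_curve <- function(sim) colMeans(sim$levels$rnap2) /
    mean(sim$levels$rnap2[, 1])
  hl_nodrug <- half_life_by_interpolation(
    days, mean_curve(simulate_population(mk(list()), days)))$halflife_days
  hl_chx <- half_life_by_interpolation(
    days, mean_curve(simulate_population(mk(chx), days)))$halflife_days
  rec <- decompose_production(hl_chx, hl_nodrug)
  expect_equal(rec$k_deg_per_day, d, tolerance = 0.05)
  expect_equal(rec$production_per_day, p, tolerance = 0.05)
})

test_that("survival is nonincreasing and seed-reproducible", {
  for (seed in 1:5) {
    sim <- simulate_population(default_death_model(n_spores = 300, seed = seed),
                               seq(0, 80, 5))
    expect_true(all(diff(sim$survival$fraction_alive) <= 0))
  }
  a <- simulate_population(default_death_model(n_spores = 100, seed = 3),
                           c(0, 20, 40))
  b <- simulate_population(default_death_model(n_spores = 100, seed = 3),
                           c(0, 20, 40))
  expect_identical(a, b)
})

test_that("transcription inhibition kills fast while the polymerase pool persists", {
  thio <- list(list(start_day = 0, end_day = Inf, condition = "thiolutin",
                    production_scale = c(rnap2 = 0, fast_transcript = 0)))
  params <- default_death_model(n_spores = 1000, seed = 2,
                                drug_schedule = thio)
  sim <- simulate_population(params, c(0, 0.5, 1))
  # half the population dead within ~12 h
  expect_lt(abs(sim$survival$fraction_alive[2] - 0.5), 0.1)
  # yet RNAP II retains more than half its initial level after a day
  expect_gt(median(sim$levels$rnap2[, 3]), 0.5)
})

test_that("ageing shifts the implied dose-response toward higher glucose", {
  cfg <- generator_config()
  params <- default_death_model(n_spores = 4000, seed = 9)
  gluc <- 10^seq(-3.7, 0.3, length.out = 12)
  shift <- predicted_landscape_shift(params, c(0, 15, 30), cfg,
                                     capacity_species = "rnap2",
                                     glucose_levels = gluc)

  # at age 0 the curve equals the generator's population curve for the
  # same capacity sample, by construction
  sim <- simulate_population(params, c(0, 15, 30))
  cap0 <- cfg$capacity_median * sim$levels$rnap2[, 1]
  manual <- vapply(gluc, function(g)
    mean(germination_probability(cap0, g, cfg)), numeric(1))
  expect_equal(shift$fraction[shift$age_days == 0], manual, tolerance = 1e-12)

  # c50 of the implied curve strictly increases with age
  c50_at <- function(a) {
    sub <- shift[shift$age_days == a, ]
    fit_dose_response(data.frame(glucose_pct = sub$glucose_pct,
                                 fraction = pmin(pmax(sub$fraction, 0), 1)))$c50
  }
  c50s <- vapply(c(0, 15, 30), c50_at, numeric(1))
  expect_true(all(diff(c50s) > 0))

  # at saturating glucose the implied fraction equals survival
  at2 <- predicted_landscape_shift(params, c(0, 15, 30), cfg,
                                   glucose_levels = 2)
  expect_equal(at2$fraction, sim$survival$fraction_alive, tolerance = 0.01)

  expect_error(predicted_landscape_shift(params, 0, cfg,
                                         capacity_species = "nope"),
               "not in the model")
})
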