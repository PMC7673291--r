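test_that("population generator handles the empty case and validates inputs", {
  cfg <- generator_config(n_bags = 0)
  expect_equal(nrow(generate_population(cfg, seed = 1)), 0L)
  expect_error(generator_config(capacity_cv = -0.1), "cv")
  expect_error(generate_population(generator_config(), seed = 1,
                                   glucose_levels = c(0.01, -1)),
               "positive")
  expect_error(generator_config(landscape_params = list(
    c50_ref = 0.003, hill_slope = 25, floor_prob = 0.5, ceiling_prob = 0.2,
    capacity_coupling = 2)), "ceiling")
})

test_that("identical config and seed give identical populations", {
  cfg <- generator_config(n_bags = 100, glucose_levels = c(0.001, 2))
  a <- generate_population(cfg, seed = 42)
  b <- generate_population(cfg, seed = 42)
  expect_identical(a, b)
  c2 <- generate_population(cfg, seed = 43)
  expect_false(identical(a$capacity_true, c2$capacity_true))
})

test_that("nearly every bag germinates at saturating glucose", {
  cfg <- generator_config(n_bags = 300, glucose_levels = 2)
  rec <- generate_population(cfg, seed = 7)
  expect_gt(mean(rec$germinated), 0.97)
})

test_that("generative germination probability is monotone in glucose and capacity", {
  cfg <- generator_config()
  caps <- exp(seq(log(300), log(30000), length.out = 40))
  glucs <- 10^seq(-4, 0.3, length.out = 40)
  for (cap in caps[c(1, 20, 40)]) {
    p <- germination_probability(cap, glucs, cfg)
    expect_true(all(diff(p) >= -1e-12))
  }
  for (g in glucs[c(1, 20, 40)]) {
    p <- germination_probability(caps, g, cfg)
    expect_true(all(diff(p) >= -1e-12))
  }
})

test_that("empirical germinated fraction concentrates on the generative mean", {
  cfg <- generator_config(n_bags = 10000, glucose_levels = c(0.001, 0.003, 0.01))
  rec <- generate_population(cfg, seed = 11)
  for (g in cfg$glucose_levels) {
    sub <- rec[rec$glucose_pct == g, ]
    p_true <- mean(germination_probability(sub$capacity_true, g, cfg))
    se <- sqrt(p_true * (1 - p_true) / nrow(sub))
    expect_lt(abs(mean(sub$germinated) - p_true), 3 * se)
  }
})

test_that("record conservation: counts match and dead/dormant partition is exclusive", {
  cfg <- generator_config(n_bags = 50)
  rec <- generate_population(cfg, seed = 3)
  expect_equal(nrow(rec), 50L * length(cfg$glucose_levels))
  expect_true(all(rec$dead %in% c(TRUE, FALSE)))
  expect_true(all(xor(is.na(rec$germination_time_min), rec$germinated)))
  aged <- generate_ageing_series(cfg, c(0, 40), seed = 3)[["40"]]
  expect_true(all(aged$dead == !aged$germinated))
})

test_that("trace generator reproduces closed forms in the noise-free limit", {
  # dead bag, zero drift, zero noise: constant at baseline
  cfg <- quiet_config(n_bags = 1, glucose_levels = 2)
  cfg$trace_params$dead_drift_per_h <- 0
  rec <- generate_population(cfg, seed = 1)
  rec$dead <- TRUE
  tr <- generate_traces(rec, cfg, seed = 1)[[1]]
  expect_equal(tr$fluor_au, rep(tr$fluor_au[1], length(tr$times_h)))

  # dormant bag, lag 8 h, rate 0.05/h: baseline * exp(0.05 (t - 8)) past lag
  cfg$trace_params$lag_h_range <- c(8, 8)
  cfg$trace_params$production_rate_mean_per_h <- 0.05
  cfg$trace_params$production_rate_sd <- 0
  rec$dead <- FALSE
  tr <- generate_traces(rec, cfg, seed = 1)[[1]]
  expected <- tr$baseline_au * exp(0.05 * pmax(0, tr$times_h - 8))
  expect_equal(tr$fluor_au, expected, tolerance = 1e-12)

  expect_equal(generate_traces(rec[0, ], cfg, seed = 1), list())
  bad <- cfg; bad$trace_params$frame_interval_min <- -5
  expect_error(generate_traces(rec, bad, seed = 1))
})

test_that("dormant traces rise while dead traces do not, across seeds", {
  cfg <- generator_config(n_bags = 6, glucose_levels = 2)
  rec <- generate_population(cfg, seed = 1)
  rec$dead <- rep(c(FALSE, TRUE), 3)
  for (seed in 1:20) {
    traces <- generate_traces(rec, cfg, seed = seed)
    final_fold <- vapply(traces, function(tr) mean(utils::tail(tr$fold_change, 6)),
                         numeric(1))
    expect_gt(mean(final_fold[!rec$dead]), 1.3)
    expect_true(all(final_fold[rec$dead] < 1.1))
  }
})

test_that("ageing series obeys the configured exponential decay", {
  # balanced rates: no net decay
  cfg <- quiet_config(n_bags = 200)
  cfg$ageing$net_halflife_days <- Inf
  series <- generate_ageing_series(cfg, c(0, 14, 28), seed = 5)
  m0 <- mean(series[["0"]]$rnap2_level_au)
  expect_equal(mean(series[["28"]]$rnap2_level_au), m0, tolerance = 1e-10)

  # 14-day net half-life: day-14 mean is half the day-0 mean, noise-free
  cfg <- quiet_config(n_bags = 200)
  series <- generate_ageing_series(cfg, c(0, 14), seed = 5)
  expect_equal(mean(series[["14"]]$rnap2_level_au),
               0.5 * mean(series[["0"]]$rnap2_level_au), tolerance = 1e-10)

  # translation inhibition with production_scale 0 decays at the full
  # degradation rate
  series <- generate_ageing_series(cfg, c(0, 8.4), seed = 5,
                                   condition = "cycloheximide")
  expect_equal(mean(series[["8.4"]]$rnap2_level_au),
               0.5 * mean(series[["0"]]$rnap2_level_au), tolerance = 1e-10)

  expect_error(generate_ageing_series(cfg, c(0, 7), seed = 1,
                                      condition = "caffeine"),
               "unknown condition")
  # survival fraction nonincreasing in age
  series <- generate_ageing_series(generator_config(n_bags = 500),
                                   seq(0, 80, 10), seed = 9)
  alive <- vapply(series, function(s) mean(!s$dead), numeric(1))
  expect_true(all(diff(alive) <= 0))
})

test_that("priming generator: memory decays with delay and zero-variance is exact", {
  cfg <- generator_config(n_bags = 150)
  long <- generate_priming_dataset(cfg, delay_h = 96, seed = 2)
  expect_lt(abs(mean(long$primed_times) - mean(long$unprimed_times)), 10)

  cfg0 <- generator_config(n_bags = 20,
                           germination_time_params = list(
                             mean_unprimed_min = 200, mean_primed_min = 120,
                             sd_min = 0, priming_full_delay_h = 16,
                             priming_gone_delay_h = 96))
  exact <- generate_priming_dataset(cfg0, delay_h = 16, seed = 2)
  expect_equal(exact$primed_times, rep(120, 20))
  expect_equal(exact$unprimed_times, rep(200, 20))

  # expression tables anchored at the 0-h timepoint
  pr <- generate_priming_dataset(cfg, delay_h = 16, seed = 2)
  ratio <- module_expression_ratio(pr$expr_primed, pr$expr_unprimed,
                                   pr$module_map)
  expect_equal(unname(ratio[, "0"]), rep(1, nrow(ratio)))
})
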