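#' Generate a synthetic spore-bag population
#'
#' Draws `n_bags` spore bags per glucose level. Capacity is lognormal
#' (median `capacity_median`, CV `capacity_cv`); GFP inducibility is
#' capacity with multiplicative measurement noise; RNAP II, 18S rRNA and
#' total-RNA-rate proxies are lognormal markers correlated with capacity at
#' the configured Pearson targets on the log scale. Germination is Bernoulli
#' with the generative landscape probability
#' ([germination_probability()]), and germination times are truncated
#' normal, censored at the observation horizon.
#'
#' @param config a [generator_config()].
#' @param seed integer seed; identical `(config, seed)` give identical
#'   output.
#' @param glucose_levels optional override of `config$glucose_levels`.
#' @return a `data.frame` of class `spore_bag_records`, one row per bag,
#'   with unit-suffixed columns (`gfp_inducibility_au`, `glucose_pct`,
#'   `germination_time_min`, ...). `germination_time_min` is `NA` for
#'   un-germinated bags; the censoring horizon is recorded in the
#'   `censor_horizon_min` attribute.
#' @export
generate_population <- function(config, seed = config$seed,
                                glucose_levels = config$glucose_levels) {
  validate_generator_config(config)
  if (any(glucose_levels <= 0)) stop("glucose levels must be strictly positive")
  set.seed(as.integer(seed))
  n_per <- config$n_bags
  n <- n_per * length(glucose_levels)
  if (n == 0) return(empty_records(config))

  glucose <- rep(glucose_levels, each = n_per)
  cp <- lnorm_pars(config$capacity_median, max(config$capacity_cv, 1e-12))
  z_cap <- stats::rnorm(n)
  capacity <- exp(cp$meanlog + cp$sdlog * z_cap)

  corr_marker <- function(median, rho) {
    mp <- lnorm_pars(median, max(config$capacity_cv, 1e-12))
    z <- rho * z_cap + sqrt(1 - rho^2) * stats::rnorm(n)
    exp(mp$meanlog + mp$sdlog * z)
  }
  rnap2 <- corr_marker(config$rnap2_median, config$rnap2_corr)
  rrna <- corr_marker(config$rnap2_median / 2, config$rrna_corr)
  total_rna <- corr_marker(config$rnap2_median / 4, config$total_rna_corr)

  gfp <- pmax(capacity * (1 + stats::rnorm(n, 0, config$marker_cv)), 0)

  p <- germination_probability(capacity, glucose, config)
  germinated <- stats::rbinom(n, 1, p) == 1

  gt <- config$germination_time_params
  times <- rep(NA_real_, n)
  times[germinated] <- rtruncnorm_lower(sum(germinated),
                                        gt$mean_unprimed_min, gt$sd_min)
  censored <- !is.na(times) & times > config$censor_horizon_min
  germinated[censored] <- FALSE
  times[censored] <- NA_real_

  out <- data.frame(
    bag_id = sprintf("bag_%05d", seq_len(n)),
    capacity_true = capacity,
    gfp_inducibility_au = gfp,
    rnap2_level_au = rnap2,
    rrna_level_au = rrna,
    total_rna_rate_au = total_rna,
    glucose_pct = glucose,
    germinated = germinated,
    germination_time_min = times,
    age_days = 0,
    condition = "none",
    primed = FALSE,
    dead = FALSE,
    stringsAsFactors = FALSE)
  attr(out, "censor_horizon_min") <- config$censor_horizon_min
  class(out) <- c("spore_bag_records", "data.frame")
  out
}

empty_records <- function(config) {
  out <- data.frame(bag_id = character(), capacity_true = numeric(),
                    gfp_inducibility_au = numeric(), rnap2_level_au = numeric(),
                    rrna_level_au = numeric(), total_rna_rate_au = numeric(),
                    glucose_pct = numeric(), germinated = logical(),
                    germination_time_min = numeric(), age_days = numeric(),
                    condition = character(), primed = logical(),
                    dead = logical(), stringsAsFactors = FALSE)
  attr(out, "censor_horizon_min") <- config$censor_horizon_min
  class(out) <- c("spore_bag_records", "data.frame")
  out
}

#' Generate post-glucose fluorescence traces
#'
#' For each record, emits a fluorescence time course after a saturating
#' glucose pulse at time 0. Dormant bags (`dead == FALSE`) stay flat at
#' their baseline for a lag drawn uniformly from `lag_h_range`, then grow
#' exponentially at a per-bag rate drawn from
#' `Normal(production_rate_mean_per_h, production_rate_sd)`. Dead bags
#' drift exponentially at `dead_drift_per_h` (<= 0). Gaussian noise
#' (`noise_sd_au`) is added and the result floored at `background_au`.
#' If `trace_params$germination_fold` is set, dormant traces are truncated
#' once their noiseless fold change reaches it (germination).
#'
#' @param records a `spore_bag_records` data frame; the `dead` column is
#'   the ground truth (alive = would germinate at 2% glucose).
#' @param config a [generator_config()].
#' @param seed integer seed.
#' @return a list of [trace_series()] objects.
#' @export
generate_traces <- function(records, config, seed = config$seed) {
  validate_generator_config(config)
  tp <- config$trace_params
  if (tp$frame_interval_min <= 0) stop("frame interval must be positive")
  if (nrow(records) == 0) return(list())
  set.seed(as.integer(seed))

  times <- seq(0, tp$duration_h, by = tp$frame_interval_min / 60)
  n <- nrow(records)
  lags <- stats::runif(n, tp$lag_h_range[1], tp$lag_h_range[2])
  rates <- stats::rnorm(n, tp$production_rate_mean_per_h, tp$production_rate_sd)
  noise <- matrix(stats::rnorm(n * length(times), 0, tp$noise_sd_au),
                  nrow = n)

  lapply(seq_len(n), function(i) {
    dead_i <- isTRUE(records$dead[i])
    baseline <- max(records$rnap2_level_au[i], tp$background_au)
    if (dead_i) {
      signal <- baseline * exp(tp$dead_drift_per_h * times)
      germ_h <- NA_real_
      tt <- times
    } else {
      fold <- exp(rates[i] * pmax(0, times - lags[i]))
      signal <- baseline * fold
      germ_h <- NA_real_
      tt <- times
      if (!is.null(tp$germination_fold) && rates[i] > 0) {
        germ_h <- lags[i] + log(tp$germination_fold) / rates[i]
        keep <- times <= germ_h
        tt <- times[keep]
        signal <- signal[keep]
      }
    }
    fluor <- pmax(signal + noise[i, seq_along(tt)], tp$background_au)
    trace_series(bag_id = records$bag_id[i], times_h = tt, fluor_au = fluor,
                 baseline_au = baseline, germination_time_h = germ_h,
                 dead_truth = dead_i)
  })
}

#' Generate an ageing series of spore-bag populations
#'
#' Emulates populations aged in water under a drug condition and sampled at
#' the given days. Capacity and RNAP II decay exponentially at the
#' condition's rate: without drugs the net rate is
#' `ln2 / net_halflife_days` (degradation minus production); with the
#' production scale set to 0 (cycloheximide, thiolutin) decay proceeds at
#' the full degradation rate `ln2 / degradation_halflife_days`. Each bag
#' carries a lognormal initial-capacity/threshold ratio and is dead at day
#' `t` once its capacity has decayed below its threshold (or it was killed
#' by the condition's extra hazard, e.g. fast thiolutin killing).
#'
#' @param config a [generator_config()].
#' @param sample_days nonnegative, sorted observation days.
#' @param seed integer seed.
#' @param condition one of `names(config$drug_effects)`.
#' @return named list mapping day to a `spore_bag_records` data frame.
#' @export
generate_ageing_series <- function(config, sample_days, seed = config$seed,
                                   condition = "none") {
  validate_generator_config(config)
  if (!condition %in% names(config$drug_effects))
    stop("unknown condition label: ", condition)
  if (any(sample_days < 0) || is.unsorted(sample_days))
    stop("sample_days must be nonnegative and sorted")
  set.seed(as.integer(seed))

  n <- config$n_bags
  cap0 <- rlnorm_med_cv(n, config$capacity_median, config$capacity_cv)
  rnap0 <- rlnorm_med_cv(n, config$rnap2_median, config$capacity_cv)
  ratio <- rlnorm_med_cv(n, config$death$ratio_median, config$death$ratio_cv)

  d <- log(2) / config$ageing$degradation_halflife_days
  k_net <- log(2) / config$ageing$net_halflife_days   # 0 when Inf
  production <- d - k_net
  de <- config$drug_effects[[condition]]
  rate <- d - de$production_scale * production
  extra_per_day <- de$extra_death_rate_per_h * 24
  extra_death_day <- if (extra_per_day > 0)
    stats::rexp(n, extra_per_day) else rep(Inf, n)
  # capacity crosses its threshold when exp(-rate * t) < 1/ratio
  threshold_day <- if (rate > 0) log(ratio) / rate else rep(Inf, n)
  death_day <- pmin(threshold_day, extra_death_day)

  gt <- config$germination_time_params
  out <- lapply(sample_days, function(day) {
    decay <- exp(-rate * day)
    cap <- cap0 * decay
    rnap <- rnap0 * decay * (1 + stats::rnorm(n, 0, config$marker_cv))
    dead <- death_day <= day
    germ_time <- rep(NA_real_, n)
    germ_time[!dead] <- rtruncnorm_lower(sum(!dead), gt$mean_unprimed_min,
                                         gt$sd_min)
    rec <- data.frame(
      bag_id = sprintf("bag_%05d", seq_len(n)),
      capacity_true = cap,
      gfp_inducibility_au = pmax(cap * (1 + stats::rnorm(n, 0, config$marker_cv)), 0),
      rnap2_level_au = pmax(rnap, 0),
      rrna_level_au = pmax(rnap0 * decay, 0),
      total_rna_rate_au = pmax(rnap0 * decay / 4, 0),
      glucose_pct = 2,
      germinated = !dead,
      germination_time_min = germ_time,
      age_days = day,
      condition = condition,
      primed = FALSE,
      dead = dead,
      stringsAsFactors = FALSE)
    attr(rec, "censor_horizon_min") <- config$censor_horizon_min
    class(rec) <- c("spore_bag_records", "data.frame")
    rec
  })
  names(out) <- as.character(sample_days)
  out
}

priming_effect <- function(delay_h, config) {
  gt <- config$germination_time_params
  full <- gt$priming_full_delay_h
  gone <- gt$priming_gone_delay_h
  if (delay_h <= full) 1
  else if (delay_h >= gone) 0
  else 1 - (delay_h - full) / (gone - full)
}

#' Generate a synthetic priming dataset
#'
#' Two-step glucose experiment: bags primed by a sub-germinating glucose
#' pulse germinate faster when glucose is stepped up `delay_h` hours later.
#' Germination times are truncated normal; the primed mean relaxes linearly
#' from `mean_primed_min` back to `mean_unprimed_min` between
#' `priming_full_delay_h` and `priming_gone_delay_h` (memory gone by four
#' days). Also emits gene x timepoint expression tables (primed and
#' unprimed) whose module-structured fold changes relax to parity by the
#' longest timepoint, for the module-ratio analysis.
#'
#' @param config a [generator_config()].
#' @param delay_h hours between the priming pulse and the glucose step-up.
#' @param seed integer seed.
#' @param n_genes_per_module genes simulated per transcriptional module.
#' @return list with `primed_times`, `unprimed_times` (minutes),
#'   `expr_primed`, `expr_unprimed` (gene x timepoint matrices, columns
#'   "0","16","48","96" hours), and `module_map` (data.frame gene, module).
#' @export
generate_priming_dataset <- function(config, delay_h = 16,
                                     seed = config$seed,
                                     n_genes_per_module = 8) {
  validate_generator_config(config)
  if (delay_h < 0) stop("delay_h must be >= 0")
  set.seed(as.integer(seed))
  gt <- config$germination_time_params
  eff <- priming_effect(delay_h, config)
  primed_mean <- gt$mean_unprimed_min -
    (gt$mean_unprimed_min - gt$mean_primed_min) * eff
  n <- config$n_bags
  primed_times <- rtruncnorm_lower(n, primed_mean, gt$sd_min)
  unprimed_times <- rtruncnorm_lower(n, gt$mean_unprimed_min, gt$sd_min)

  modules <- c("carbon_metabolism", "stress_response",
               "ribosome_biogenesis", "spore_wall")
  amp <- c(carbon_metabolism = 2.0, stress_response = 0.5,
           ribosome_biogenesis = 1.5, spore_wall = 0.7)
  relax <- c("0" = 0, "16" = 1, "48" = 0.4, "96" = 0)  # priming transient
  timepoints <- names(relax)
  genes <- unlist(lapply(modules, function(m)
    paste0(m, "_g", seq_len(n_genes_per_module))))
  module_map <- data.frame(gene = genes,
                           module = rep(modules, each = n_genes_per_module),
                           stringsAsFactors = FALSE)
  base <- rlnorm_med_cv(length(genes), 100, 0.5)
  expr_unprimed <- matrix(rep(base, length(timepoints)),
                          nrow = length(genes),
                          dimnames = list(genes, timepoints))
  fold <- vapply(timepoints, function(tp)
    1 + (amp[module_map$module] - 1) * relax[tp], numeric(length(genes)))
  expr_primed <- expr_unprimed * fold
  list(primed_times = primed_times, unprimed_times = unprimed_times,
       expr_primed = expr_primed, expr_unprimed = expr_unprimed,
       module_map = module_map)
}
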