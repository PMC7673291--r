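#' Configuration for the synthetic spore-bag data generator
#'
#' Bundles every tunable of the generative model: lognormal heterogeneity in
#' gene-expressing capacity across spore bags, a germination probability that
#' is logistic in log-glucose with a capacity-dependent half-maximal
#' concentration, exponential ageing decay of capacity and RNA polymerase II
#' level, drug perturbations that rescale production, post-glucose
#' fluorescence traces (lag, then exponential production for dormant bags;
#' flat or slowly drifting for dead bags) with additive measurement noise on
#' a background floor, and truncated-normal germination times.
#'
#' Defaults are calibrated so the generative population reproduces the
#' headline single-spore observations: a sigmoidal population dose-response
#' stepping at ~0.003% glucose between a ~10% low-glucose plateau and ~100%
#' at saturation, and a germination landscape in which, at 0.001% glucose,
#' bags with the highest inducibility germinate almost surely while bags at
#' half the maximal inducibility germinate ~10% of the time.
#'
#' @param n_bags number of spore bags per population.
#' @param capacity_median median gene-expressing capacity (a.u.).
#' @param capacity_cv lognormal coefficient of variation of capacity.
#' @param marker_cv multiplicative measurement noise CV on marker readouts.
#' @param rnap2_median median RNA polymerase II fluorescence (a.u.).
#' @param rnap2_corr target Pearson correlation (log scale) between capacity
#'   and RNAP II level.
#' @param rrna_corr,total_rna_corr target correlations for the 18S rRNA and
#'   total-RNA-rate proxies.
#' @param glucose_levels glucose concentrations (% w/v) at which populations
#'   are observed; default eight log-spaced levels spanning 0.0002%-2%.
#' @param landscape_params list with `c50_ref` (half-maximal glucose at the
#'   median capacity, % w/v), `hill_slope` (per-bag steepness),
#'   `floor_prob`, `ceiling_prob`, and `capacity_coupling` (decades of
#'   log10-c50 shift per decade of capacity; positive means higher-capacity
#'   bags need less glucose).
#' @param ageing list with `net_halflife_days` (drug-free net loss) and
#'   `degradation_halflife_days` (translation-inhibited loss).
#' @param death list with `ratio_median` and `ratio_cv`: per-bag
#'   initial-capacity/death-threshold ratio is lognormal; a bag is dead once
#'   its capacity decays below its threshold.
#' @param drug_effects named list per condition with `production_scale`
#'   (multiplies production; 0 under transcription/translation inhibition)
#'   and `extra_death_rate_per_h` (additional exponential kill rate, used
#'   for the fast thiolutin killing).
#' @param trace_params list with `lag_h_range` (hours, uniform),
#'   `production_rate_mean_per_h`, `production_rate_sd`, `dead_drift_per_h`
#'   (<= 0), `noise_sd_au`, `background_au` (fluorescence floor),
#'   `frame_interval_min`, `duration_h`, and optional `germination_fold`
#'   (fold change at which a dormant trace is truncated by germination;
#'   `NULL` disables truncation).
#' @param germination_time_params list with `mean_unprimed_min`,
#'   `mean_primed_min`, `sd_min`, and the priming-memory window
#'   `priming_full_delay_h` / `priming_gone_delay_h` (effect full up to the
#'   former, linearly gone by the latter).
#' @param censor_horizon_min observation horizon for germination (minutes).
#' @param seed default master seed; per-generator calls may override.
#'
#' @return a validated list of class `generator_config`.
#' @export
generator_config <- function(n_bags = 145,
                             capacity_median = 3000,
                             capacity_cv = 0.30,
                             marker_cv = 0.05,
                             rnap2_median = 4000,
                             rnap2_corr = 0.64,
                             rrna_corr = 0.63,
                             total_rna_corr = 0.24,
                             glucose_levels = signif(10^seq(log10(2e-4), log10(2), length.out = 8), 3),
                             landscape_params = list(c50_ref = 0.003,
                                                     hill_slope = 25,
                                                     floor_prob = 0.1,
                                                     ceiling_prob = 1.0,
                                                     capacity_coupling = 2.2),
                             ageing = list(net_halflife_days = 14,
                                           degradation_halflife_days = 8.4),
                             death = list(ratio_median = 6.6, ratio_cv = 0.3),
                             drug_effects = list(
                               none          = list(production_scale = 1, extra_death_rate_per_h = 0),
                               cycloheximide = list(production_scale = 0, extra_death_rate_per_h = 0),
                               thiolutin     = list(production_scale = 0, extra_death_rate_per_h = log(2) / 12)),
                             trace_params = list(lag_h_range = c(5, 10),
                                                 production_rate_mean_per_h = 0.031,
                                                 production_rate_sd = 0.010,
                                                 dead_drift_per_h = -0.003,
                                                 noise_sd_au = 100,
                                                 background_au = 2500,
                                                 frame_interval_min = 10,
                                                 duration_h = 24,
                                                 germination_fold = NULL),
                             germination_time_params = list(mean_unprimed_min = 200,
                                                            mean_primed_min = 120,
                                                            sd_min = 30,
                                                            priming_full_delay_h = 16,
                                                            priming_gone_delay_h = 96),
                             censor_horizon_min = 960,
                             seed = 1L) {
  config <- list(n_bags = n_bags, capacity_median = capacity_median,
                 capacity_cv = capacity_cv, marker_cv = marker_cv,
                 rnap2_median = rnap2_median, rnap2_corr = rnap2_corr,
                 rrna_corr = rrna_corr, total_rna_corr = total_rna_corr,
                 glucose_levels = glucose_levels,
                 landscape_params = landscape_params, ageing = ageing,
                 death = death, drug_effects = drug_effects,
                 trace_params = trace_params,
                 germination_time_params = germination_time_params,
                 censor_horizon_min = censor_horizon_min, seed = seed)
  class(config) <- "generator_config"
  validate_generator_config(config)
}

#' Validate a generator configuration
#'
#' Checks the structural invariants: probabilities in \[0, 1\] with
#' ceiling >= floor, strictly positive half-lives, rates and scales
#' (the dead-trace drift may be <= 0), positive glucose levels, and
#' nonnegative counts and CVs.
#'
#' @param config a `generator_config` list.
#' @return the config, invisibly usable; errors on violation.
#' @export
validate_generator_config <- function(config) {
  if (!is_count(config$n_bags)) stop("n_bags must be a nonnegative integer")
  stop_if_not_scalar_pos(config$capacity_median, "capacity_median")
  if (!is.numeric(config$capacity_cv) || config$capacity_cv < 0)
    stop("capacity_cv must be >= 0")
  if (config$marker_cv < 0) stop("marker_cv must be >= 0")
  if (any(!is.finite(config$glucose_levels)) || any(config$glucose_levels <= 0))
    stop("glucose_levels must be strictly positive")
  lp <- config$landscape_params
  stop_if_not_scalar_pos(lp$c50_ref, "c50_ref")
  stop_if_not_scalar_pos(lp$hill_slope, "hill_slope")
  if (lp$floor_prob < 0 || lp$floor_prob > 1 ||
      lp$ceiling_prob < 0 || lp$ceiling_prob > 1)
    stop("floor_prob and ceiling_prob must lie in [0, 1]")
  if (lp$ceiling_prob < lp$floor_prob)
    stop("ceiling_prob must be >= floor_prob")
  if (!is.finite(lp$capacity_coupling)) stop("capacity_coupling must be finite")
  stop_if_not_scalar_pos(config$ageing$degradation_halflife_days,
                         "degradation_halflife_days")
  if (!(is.numeric(config$ageing$net_halflife_days) &&
        config$ageing$net_halflife_days > 0))
    stop("net_halflife_days must be > 0 (use Inf for balanced rates)")
  stop_if_not_scalar_pos(config$death$ratio_median, "death ratio_median")
  if (config$death$ratio_cv < 0) stop("death ratio_cv must be >= 0")
  for (nm in names(config$drug_effects)) {
    de <- config$drug_effects[[nm]]
    if (de$production_scale < 0) stop("production_scale must be >= 0")
    if (de$extra_death_rate_per_h < 0) stop("extra_death_rate_per_h must be >= 0")
  }
  tp <- config$trace_params
  if (length(tp$lag_h_range) != 2 || tp$lag_h_range[1] > tp$lag_h_range[2] ||
      any(tp$lag_h_range < 0))
    stop("lag_h_range must be nonnegative and ordered")
  stop_if_not_scalar_pos(tp$production_rate_mean_per_h, "production_rate_mean_per_h")
  if (tp$production_rate_sd < 0) stop("production_rate_sd must be >= 0")
  if (tp$dead_drift_per_h > 0) stop("dead_drift_per_h must be <= 0")
  if (tp$noise_sd_au < 0) stop("noise_sd_au must be >= 0")
  stop_if_not_scalar_pos(tp$background_au, "background_au")
  stop_if_not_scalar_pos(tp$frame_interval_min, "frame_interval_min")
  stop_if_not_scalar_pos(tp$duration_h, "duration_h")
  gt <- config$germination_time_params
  stop_if_not_scalar_pos(gt$mean_unprimed_min, "mean_unprimed_min")
  stop_if_not_scalar_pos(gt$mean_primed_min, "mean_primed_min")
  if (gt$sd_min < 0) stop("sd_min must be >= 0")
  stop_if_not_scalar_pos(config$censor_horizon_min, "censor_horizon_min")
  config
}

#' Generative germination probability of a spore bag
#'
#' The probability that a bag with gene-expressing capacity `capacity`
#' germinates at glucose concentration `glucose_pct`:
#' `floor + (ceiling - floor) / (1 + (c50(capacity)/glucose)^hill)`,
#' where `log10 c50(capacity)` decreases linearly in `log10 capacity` with
#' slope `capacity_coupling`. Monotone nondecreasing in both glucose and
#' capacity.
#'
#' @param capacity capacity values (a.u.), vectorized.
#' @param glucose_pct glucose concentration (% w/v), vectorized.
#' @param config a `generator_config`.
#' @return germination probabilities.
#' @export
germination_probability <- function(capacity, glucose_pct, config) {
  lp <- config$landscape_params
  if (any(glucose_pct <= 0)) stop("glucose_pct must be strictly positive")
  c50 <- lp$c50_ref * (capacity / config$capacity_median)^(-lp$capacity_coupling)
  lp$floor_prob + (lp$ceiling_prob - lp$floor_prob) /
    (1 + (c50 / glucose_pct)^lp$hill_slope)
}
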