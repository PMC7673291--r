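#' Parameters of one molecular species in the threshold-death model
#'
#' Each species is a per-spore pool of a molecule required for gene
#' expression (e.g. RNA polymerase II, or a hypothesized fast-degrading
#' transcript). Degradation is first-order. Production is either
#' `"zeroth_order"` (a constant supply `production_per_day`, expressed
#' relative to the initial population median, so the pool relaxes toward
#' `p/d`) or `"first_order"` (production proportional to the current
#' level, so the pool decays exponentially at the net rate `d - p`; this
#' is the mode whose cohort means obey the ln2 half-life arithmetic of
#' [decompose_production()]).
#'
#' @param name species label.
#' @param production_per_day relative production rate (1/day, >= 0).
#' @param degradation_per_day first-order degradation rate (1/day, > 0).
#' @param threshold_frac death threshold as a fraction of the initial
#'   population median, in (0, 1).
#' @param initial_cv lognormal CV of initial levels across spores.
#' @param production_model `"zeroth_order"` or `"first_order"`.
#' @return object of class `species_params`.
#' @export
species_params <- function(name, production_per_day, degradation_per_day,
                           threshold_frac, initial_cv = 0.3,
                           production_model = c("zeroth_order", "first_order")) {
  production_model <- match.arg(production_model)
  stop_if_not_scalar_pos(degradation_per_day, "degradation_per_day")
  stop_if_not_scalar_pos(production_per_day, "production_per_day",
                         allow_zero = TRUE)
  if (threshold_frac <= 0 || threshold_frac >= 1)
    stop("threshold_frac must lie in (0, 1)")
  if (initial_cv < 0) stop("initial_cv must be >= 0")
  structure(list(name = name, production_per_day = production_per_day,
                 degradation_per_day = degradation_per_day,
                 threshold_frac = threshold_frac, initial_cv = initial_cv,
                 production_model = production_model),
            class = "species_params")
}

#' Parameters of the threshold-death population model
#'
#' @param species list of [species_params()] (at least one).
#' @param n_spores population size (>= 1).
#' @param drug_schedule list of intervals, each a list with `start_day`,
#'   `end_day`, `condition`, and `production_scale`: a named vector
#'   (species name -> multiplier applied to that species' production
#'   inside the interval). Intervals of the same condition must not
#'   overlap.
#' @param seed integer seed.
#' @return object of class `death_model_params`.
#' @export
death_model_params <- function(species, n_spores, drug_schedule = list(),
                               seed = 1L) {
  if (length(species) == 0) stop("species list must not be empty")
  if (!all(vapply(species, inherits, logical(1), "species_params")))
    stop("species must be a list of species_params objects")
  if (!is_count(n_spores) || n_spores < 1) stop("n_spores must be >= 1")
  for (cond in unique(vapply(drug_schedule, `[[`, character(1), "condition"))) {
    iv <- Filter(function(s) s$condition == cond, drug_schedule)
    if (length(iv) > 1) {
      starts <- vapply(iv, `[[`, numeric(1), "start_day")
      ends <- vapply(iv, `[[`, numeric(1), "end_day")
      o <- order(starts)
      if (any(starts[o][-1] < ends[o][-length(ends)]))
        stop("overlapping drug-schedule intervals for condition ", cond)
    }
  }
  names(species) <- vapply(species, `[[`, character(1), "name")
  structure(list(species = species, n_spores = n_spores,
                 drug_schedule = drug_schedule, seed = as.integer(seed)),
            class = "death_model_params")
}

#' Closed-form death time under constant production and decay
#'
#' For a pool obeying `M(t) = p/d + (M0 - p/d) exp(-d t)` (zeroth-order
#' production `p`, first-order degradation `d`), the time at which the
#' pool crosses the death threshold `T`:
#' `t* = (1/d) ln((M0 - p/d) / (T - p/d))` when `T > p/d`; infinite when
#' the steady state `p/d` sits at or above the threshold; 0 when the pool
#' starts at or below it.
#'
#' @param M0 initial level(s), vectorized.
#' @param p production rate (a.u./day).
#' @param d degradation rate (1/day, > 0).
#' @param threshold death threshold (a.u.).
#' @return death time(s) in days (possibly 0 or `Inf`).
#' @export
death_time_closed_form <- function(M0, p, d, threshold) {
  stop_if_not_scalar_pos(d, "d")
  stop_if_not_scalar_pos(p, "p", allow_zero = TRUE)
  ss <- p / d
  out <- rep(Inf, length(M0))
  out[M0 <= threshold] <- 0
  open <- M0 > threshold & threshold > ss
  out[open] <- log((M0[open] - ss) / (threshold - ss)) / d
  out
}

# level after `dt` days within one constant-production segment
species_level_after <- function(M, p_eff, d, dt, model) {
  if (model == "first_order") M * exp((p_eff - d) * dt)
  else p_eff / d + (M - p_eff / d) * exp(-d * dt)
}

# crossing time of `threshold` within a segment of length dt (Inf if none)
species_crossing <- function(M, p_eff, d, dt, threshold, model) {
  if (model == "first_order") {
    k <- d - p_eff
    tc <- if (k <= 0) rep(Inf, length(M)) else log(M / threshold) / k
    tc[M <= threshold] <- 0
  } else {
    tc <- death_time_closed_form(M, p_eff, d, threshold)
  }
  ifelse(tc <= dt, tc, Inf)
}

#' Forward-simulate the threshold-death population model
#'
#' Per spore, initial levels of each species are lognormal (median 1, the
#' species' CV); levels evolve piecewise-analytically across the
#' drug-schedule segments (drugs rescale production only); a spore dies at
#' the first time any species crosses its threshold. For homogeneous
#' populations (CV 0) the survival curve is a step at the closed-form
#' death time.
#'
#' @param params a [death_model_params()].
#' @param sample_days days at which survival and levels are reported.
#' @return list with `death_days` (per spore, `Inf` if immortal),
#'   `survival` (data.frame `day`, `fraction_alive`), and `levels`
#'   (per species, a `n_spores x length(sample_days)` matrix).
#' @export
simulate_population <- function(params, sample_days) {
  if (!inherits(params, "death_model_params")) stop("invalid params")
  if (any(sample_days < 0)) stop("sample_days must be nonnegative")
  set.seed(params$seed)
  n <- params$n_spores
  ends <- vapply(params$drug_schedule, `[[`, numeric(1), "end_day")
  horizon <- max(sample_days, ends[is.finite(ends)], 1e-9)
  # segment boundaries from the schedule
  bounds <- sort(unique(c(0, horizon,
                          unlist(lapply(params$drug_schedule, function(s)
                            c(s$start_day, min(s$end_day, horizon)))))))
  bounds <- bounds[bounds <= horizon]

  death_days <- rep(Inf, n)
  levels <- list()
  for (sp in params$species) {
    M0 <- rlnorm_med_cv(n, 1, sp$initial_cv)
    M <- M0
    lvl <- matrix(NA_real_, n, length(sample_days))
    sp_death <- rep(Inf, n)
    for (k in seq_len(length(bounds) - 1)) {
      t0 <- bounds[k]; t1 <- bounds[k + 1]; dt <- t1 - t0
      scale <- 1
      for (s in params$drug_schedule) {
        if (s$start_day <= t0 && t1 <= s$end_day &&
            sp$name %in% names(s$production_scale))
          scale <- scale * s$production_scale[[sp$name]]
      }
      p_eff <- sp$production_per_day * scale
      d <- sp$degradation_per_day
      tc <- species_crossing(M, p_eff, d, dt, sp$threshold_frac,
                             sp$production_model)
      sp_death <- pmin(sp_death, ifelse(is.finite(tc), t0 + tc, Inf))
      # record levels at sample days inside this segment
      in_seg <- which(sample_days >= t0 & (sample_days < t1 |
                                             (t1 == horizon & sample_days <= t1)))
      for (j in in_seg)
        lvl[, j] <- species_level_after(M, p_eff, d, sample_days[j] - t0,
                                        sp$production_model)
      M <- species_level_after(M, p_eff, d, dt, sp$production_model)
    }
    # beyond the last boundary the last segment's kinetics continue
    beyond <- which(sample_days > horizon)
    for (j in beyond)
      lvl[, j] <- species_level_after(M, p_eff, d, sample_days[j] - horizon,
                                      sp$production_model)
    if (any(sample_days > horizon)) {
      tc <- species_crossing(M, p_eff, d, Inf, sp$threshold_frac,
                             sp$production_model)
      sp_death <- pmin(sp_death, ifelse(is.finite(tc), horizon + tc, Inf))
    }
    death_days <- pmin(death_days, sp_death)
    levels[[sp$name]] <- lvl
  }
  survival <- data.frame(
    day = sample_days,
    fraction_alive = vapply(sample_days, function(t) mean(death_days > t),
                            numeric(1)))
  list(death_days = death_days, survival = survival, levels = levels)
}

#' Dose-response curves implied by an ageing population
#'
#' Pushes the aged capacity distribution through the generative
#' germination landscape: at each age, surviving spores carry a capacity
#' equal to `capacity_median` times their (relative) level of the
#' designated capacity species, and the population germinated fraction at
#' each glucose concentration is the mean landscape probability over
#' surviving spores (dead spores never germinate). At age 0 this
#' reproduces the generator's population dose-response; as the capacity
#' pool decays, the implied half-maximal glucose concentration increases
#' with age.
#'
#' @param params a [death_model_params()] containing the capacity species.
#' @param age_days ages (days) at which to evaluate.
#' @param config a [generator_config()] supplying the landscape.
#' @param capacity_species name of the species identified with
#'   gene-expressing capacity.
#' @param glucose_levels concentrations to evaluate.
#' @return data.frame with `age_days`, `glucose_pct`, `fraction`.
#' @export
predicted_landscape_shift <- function(params, age_days, config,
                                      capacity_species = "rnap2",
                                      glucose_levels = config$glucose_levels) {
  if (!capacity_species %in% names(params$species))
    stop("capacity species '", capacity_species, "' not in the model")
  sim <- simulate_population(params, sort(unique(c(0, age_days))))
  days <- sim$survival$day
  lvl <- sim$levels[[capacity_species]]
  out <- do.call(rbind, lapply(age_days, function(a) {
    j <- match(a, days)
    alive <- sim$death_days > a
    capacity <- config$capacity_median * lvl[, j]
    frac <- vapply(glucose_levels, function(g) {
      p <- germination_probability(pmax(capacity, 1e-12), g, config)
      mean(p * alive)
    }, numeric(1))
    data.frame(age_days = a, glucose_pct = glucose_levels, fraction = frac)
  }))
  rownames(out) <- NULL
  out
}

#' Default two-species threshold-death model
#'
#' The package's reference parameterization: a slow RNA-polymerase-II-like
#' pool (degradation half-life 8.4 days; first-order production tuned so
#' the drug-free net half-life is 14 days; threshold 1/6.6 of the initial
#' median, placing the drug-free dormancy half-life near 38 days) and a
#' fast transcript-like pool (half-life 4 hours, production balancing
#' degradation, threshold 1/8) whose production collapses under
#' transcription inhibition, killing half the population within ~12 hours
#' while the polymerase pool is still above half its initial level.
#'
#' @param n_spores population size.
#' @param seed integer seed.
#' @param drug_schedule optional schedule (see [death_model_params()]).
#' @param initial_cv lognormal CV of initial levels.
#' @return a [death_model_params()].
#' @export
default_death_model <- function(n_spores = 1000, seed = 1L,
                                drug_schedule = list(), initial_cv = 0.3) {
  d_rnap <- log(2) / 8.4
  p_rnap <- d_rnap - log(2) / 14
  d_fast <- log(2) / (4 / 24)
  death_model_params(
    species = list(
      species_params("rnap2", p_rnap, d_rnap, threshold_frac = 1 / 6.6,
                     initial_cv = initial_cv,
                     production_model = "first_order"),
      species_params("fast_transcript", d_fast, d_fast,
                     threshold_frac = 0.125, initial_cv = initial_cv,
                     production_model = "first_order")),
    n_spores = n_spores, drug_schedule = drug_schedule, seed = seed)
}
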