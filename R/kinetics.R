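#' Fluorescence trace for one spore bag
#'
#' Container for a post-glucose fluorescence time course. Fold change is
#' fluorescence relative to the bag's baseline (its level just before
#' glucose); the baseline defaults to the mean of pre-time-zero frames when
#' any exist, otherwise the first frame.
#'
#' @param bag_id identifier.
#' @param times_h acquisition times in hours, strictly increasing.
#' @param fluor_au fluorescence (a.u.), same length as `times_h`.
#' @param baseline_au baseline fluorescence; must be > 0.
#' @param germination_time_h time of germination (hours) or `NA`.
#' @param dead_truth optional generator ground truth (logical).
#' @return an object of class `trace_series`.
#' @export
trace_series <- function(bag_id, times_h, fluor_au, baseline_au = NULL,
                         germination_time_h = NA_real_, dead_truth = NA) {
  if (length(times_h) != length(fluor_au))
    stop("times_h and fluor_au must have equal length")
  if (length(times_h) > 1 && any(diff(times_h) <= 0))
    stop("times_h must be strictly increasing")
  if (is.null(baseline_au)) {
    pre <- fluor_au[times_h < 0]
    baseline_au <- if (length(pre)) mean(pre) else fluor_au[1]
  }
  if (!is.finite(baseline_au) || baseline_au <= 0)
    stop("baseline_au must be strictly positive")
  structure(list(bag_id = bag_id, times_h = as.numeric(times_h),
                 fluor_au = as.numeric(fluor_au),
                 baseline_au = as.numeric(baseline_au),
                 fold_change = as.numeric(fluor_au) / baseline_au,
                 germination_time_h = germination_time_h,
                 dead_truth = dead_truth),
            class = "trace_series")
}

#' @export
print.trace_series <- function(x, ...) {
  cat(sprintf("<trace_series %s: %d frames, %.2f-%.2f h, baseline %.0f a.u.>\n",
              x$bag_id, length(x$times_h), min(x$times_h), max(x$times_h),
              x$baseline_au))
  invisible(x)
}

#' Detect the production lag in a fluorescence trace
#'
#' The lag is the first time at which the fold change exceeds
#' `1 + 3 * noise_sd / baseline` for `k_frames` consecutive frames. The
#' baseline noise defaults to the standard deviation of the first
#' `m_baseline_frames` frames.
#'
#' @param trace a [trace_series()].
#' @param noise_sd baseline noise (a.u.); estimated from the first frames
#'   when `NULL`.
#' @param k_frames consecutive frames required above threshold.
#' @param m_baseline_frames frames used for the noise estimate.
#' @return lag time in hours, or `NA` if the threshold is never exceeded.
#' @export
detect_lag <- function(trace, noise_sd = NULL, k_frames = 3,
                       m_baseline_frames = 6) {
  n <- length(trace$times_h)
  if (n < m_baseline_frames + k_frames)
    stop("trace shorter than m_baseline_frames + k_frames")
  if (is.null(noise_sd))
    noise_sd <- stats::sd(trace$fluor_au[seq_len(m_baseline_frames)])
  threshold <- 1 + 3 * noise_sd / trace$baseline_au
  above <- trace$fold_change > threshold
  if (k_frames > 1) {
    run <- stats::filter(as.numeric(above), rep(1, k_frames),
                         sides = 1)
    hit <- which(run == k_frames) - k_frames + 1L
  } else {
    hit <- which(above)
  }
  if (!length(hit)) return(NA_real_)
  trace$times_h[hit[1]]
}

#' Fit exponential production kinetics to a trace
#'
#' Least-squares fit of `fold_change = exp(rate * (t - lag))` for
#' `t >= lag`: the lag is located by [detect_lag()] (or supplied), the lag
#' period is excluded, and the signed rate is the slope of a linear
#' regression of log fold change on time. The fit is truncated at the
#' germination time when present. A trace is classified `producing` when
#' the rate exceeds `rate_cutoff` with `r2 > r2_cutoff`, else
#' `non_producing`.
#'
#' @param trace a [trace_series()].
#' @param fit_window optional `c(min_h, max_h)` restricting the fit.
#' @param lag_h lag in hours; detected when `NULL`.
#' @param rate_cutoff,r2_cutoff classification cutoffs (default 0.005/h and
#'   0.3; chosen to separate producing from non-producing traces whose
#'   group means differ by more than an order of magnitude).
#' @param background_au optional fluorescence floor; a trace entirely at or
#'   below it carries no kinetic information and is flagged.
#' @return an object of class `trace_fit`: list with `rate_per_h`,
#'   `lag_h`, `r2`, `classification`, `n_points`, `flag`.
#' @export
fit_trace_exponential <- function(trace, fit_window = NULL, lag_h = NULL,
                                  rate_cutoff = 0.005, r2_cutoff = 0.3,
                                  background_au = NULL) {
  t <- trace$times_h
  f <- trace$fold_change
  keep <- rep(TRUE, length(t))
  if (!is.null(fit_window))
    keep <- keep & t >= fit_window[1] & t <= fit_window[2]
  if (!is.na(trace$germination_time_h))
    keep <- keep & t <= trace$germination_time_h
  t <- t[keep]; f <- f[keep]
  if (length(t) < 5) stop("need at least 5 points in the fit window")

  if (!is.null(background_au) &&
      all(trace$fluor_au[keep] <= background_au * 1.001)) {
    return(structure(list(rate_per_h = NA_real_, lag_h = NA_real_,
                          r2 = NA_real_, classification = "non_producing",
                          n_points = length(t), flag = "zero_information"),
                     class = "trace_fit"))
  }

  if (is.null(lag_h)) {
    lag_h <- tryCatch(detect_lag(trace), error = function(e) NA_real_)
  }
  fit_idx <- if (is.na(lag_h)) seq_along(t) else which(t >= lag_h)
  if (length(fit_idx) < 3) fit_idx <- seq_along(t)
  tf <- t[fit_idx]
  yf <- log(pmax(f[fit_idx], 1e-8))

  if (stats::sd(yf) == 0) {
    rate <- 0
    r2 <- 0
  } else {
    fit <- stats::lm(yf ~ tf)
    rate <- unname(stats::coef(fit)[2])
    # noise-free inputs trigger summary.lm's perfect-fit warning; harmless
    r2 <- suppressWarnings(summary(fit)$r.squared)
  }
  producing <- is.finite(rate) && rate > rate_cutoff &&
    is.finite(r2) && r2 > r2_cutoff
  structure(list(rate_per_h = rate, lag_h = lag_h, r2 = r2,
                 classification = if (producing) "producing" else "non_producing",
                 n_points = length(fit_idx), flag = "ok"),
            class = "trace_fit")
}

#' Half-life by first-crossing linear interpolation
#'
#' Locates the first crossing of 0.5 in a decay curve normalized to 1 at
#' time 0, by linear interpolation between the bracketing samples. When no
#' sample falls at or below 0.5 the crossing is extrapolated linearly from
#' the last two samples and flagged. Ties (a sample exactly at 0.5) resolve
#' to the earlier time.
#'
#' @param sample_days sample times in days; first must be 0.
#' @param level relative level (or fraction alive, for survival curves);
#'   first must be 1.
#' @return list with `halflife_days` and `flag`
#'   (`"interpolated"`/`"extrapolated"`).
#' @export
half_life_by_interpolation <- function(sample_days, level) {
  if (is.data.frame(sample_days)) {
    level <- sample_days[[2]]
    sample_days <- sample_days[[1]]
  }
  if (length(sample_days) < 2) stop("need at least 2 samples")
  if (any(!is.finite(sample_days)) || any(!is.finite(level)))
    stop("curve contains non-finite values")
  if (sample_days[1] != 0) stop("curve must start at day 0")
  if (abs(level[1] - 1) > 1e-8) stop("curve must be normalized to 1 at day 0")
  below <- which(level <= 0.5)
  below <- below[below > 1]
  if (length(below)) {
    i <- below[1]
    t0 <- sample_days[i - 1]; t1 <- sample_days[i]
    l0 <- level[i - 1]; l1 <- level[i]
    hl <- t0 + (t1 - t0) * (l0 - 0.5) / (l0 - l1)
    return(list(halflife_days = hl, flag = "interpolated"))
  }
  n <- length(level)
  slope <- (level[n] - level[n - 1]) / (sample_days[n] - sample_days[n - 1])
  if (slope >= 0)
    stop("curve never decreases below 0.5 and does not trend downward: no crossing")
  list(halflife_days = sample_days[n] + (0.5 - level[n]) / slope,
       flag = "extrapolated")
}

#' Decompose production and degradation rates from two half-lives
#'
#' Exponential kinetics: the translation-inhibited decay reflects pure
#' degradation (`k_deg = ln2 / halflife_inhibitor`), the drug-free decay
#' the net loss (`k_net = ln2 / halflife_no_drug`); their difference is the
#' relative production rate, whose reciprocal is the characteristic
#' production time. With the measured 8.4-day (cycloheximide) and 14-day
#' (drug-free) RNAP II half-lives this gives a characteristic production
#' time of ~30.3 days.
#'
#' @param halflife_inhibitor_days half-life under translation inhibition.
#' @param halflife_no_drug_days drug-free half-life.
#' @return object of class `kinetic_rates`: `k_deg_per_day`,
#'   `k_net_per_day`, `production_per_day`,
#'   `characteristic_production_time_days` (Inf when production is 0),
#'   `flag` (`"ok"`, `"no_production"`, or `"inconsistent"` when the
#'   inhibitor half-life exceeds the drug-free one).
#' @export
decompose_production <- function(halflife_inhibitor_days,
                                 halflife_no_drug_days) {
  stop_if_not_scalar_pos(halflife_inhibitor_days, "halflife_inhibitor_days")
  stop_if_not_scalar_pos(halflife_no_drug_days, "halflife_no_drug_days")
  k_deg <- log(2) / halflife_inhibitor_days
  k_net <- log(2) / halflife_no_drug_days
  production <- k_deg - k_net
  flag <- "ok"
  if (production == 0) flag <- "no_production"
  if (production < 0) flag <- "inconsistent"
  structure(list(k_deg_per_day = k_deg, k_net_per_day = k_net,
                 production_per_day = production,
                 characteristic_production_time_days =
                   if (production > 0) 1 / production else Inf,
                 flag = flag),
            class = "kinetic_rates")
}

#' @export
print.kinetic_rates <- function(x, ...) {
  cat(sprintf(paste0("kinetic rates: k_deg %.4f/day, k_net %.4f/day, ",
                     "production %.4f/day (characteristic time %.1f days) [%s]\n"),
              x$k_deg_per_day, x$k_net_per_day, x$production_per_day,
              x$characteristic_production_time_days, x$flag))
  invisible(x)
}

#' Classify a spore bag as dormant or dead
#'
#' The operational definition drives the label: a bag that germinates
#' within the observation horizon of a saturating (2%) glucose pulse is
#' dormant (alive), otherwise dead. The trace classification
#' (producing/non-producing) is reported alongside; discordance (e.g. a
#' non-germinating bag with a producing trace) is flagged for review.
#'
#' @param fit a `trace_fit` from [fit_trace_exponential()].
#' @param germinated_at_2pct logical outcome; `NA` leaves the bag
#'   unlabeled.
#' @param horizon_h observation horizon in hours (>= 24 required).
#' @return list with `label` (`"dormant"`, `"dead"`, `"unlabeled"`),
#'   `trace_classification`, `concordant`.
#' @export
classify_dormant_dead <- function(fit, germinated_at_2pct, horizon_h = 24) {
  if (horizon_h < 24) stop("observation horizon must be at least 24 h")
  if (is.na(germinated_at_2pct))
    return(list(label = "unlabeled",
                trace_classification = fit$classification,
                concordant = NA))
  label <- if (germinated_at_2pct) "dormant" else "dead"
  concordant <- (label == "dormant") == (fit$classification == "producing")
  list(label = label, trace_classification = fit$classification,
       concordant = concordant)
}
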