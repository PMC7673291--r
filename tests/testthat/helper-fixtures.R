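# shared fixtures: all synthetic, built in code

# config with measurement noise switched off, for exactness checks
quiet_config <- function(...) {
  cfg <- generator_config(...)
  cfg$marker_cv <- 0
  cfg$trace_params$noise_sd_au <- 0
  cfg
}

# deterministic single-trace constructor: flat baseline for `lag_h`, then
# exponential growth at `rate_per_h`
make_exp_trace <- function(rate_per_h, lag_h = 0, baseline = 1000,
                           duration_h = 24, frame_h = 1 / 6,
                           noise_sd = 0, seed = 1) {
  set.seed(seed)
  t <- seq(0, duration_h, by = frame_h)
  fluor <- baseline * exp(rate_per_h * pmax(0, t - lag_h)) +
    rnorm(length(t), 0, noise_sd)
  trace_series("trace", t, fluor, baseline_au = baseline)
}

records_df <- function(marker, germinated,
                       glucose = rep(0.001, length(marker))) {
  d <- data.frame(bag_id = character(length(marker)),
                  gfp_inducibility_au = as.numeric(marker),
                  germinated = as.logical(germinated),
                  glucose_pct = as.numeric(glucose))
  if (length(marker)) d$bag_id <- paste0("b", seq_along(marker))
  structure(d, class = c("spore_bag_records", "data.frame"))
}
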