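# internal helpers shared across modules

# lognormal meanlog/sdlog from a median and a coefficient of variation
lnorm_pars <- function(median, cv) {
  stopifnot(median > 0, cv >= 0)
  list(meanlog = log(median), sdlog = sqrt(log(1 + cv^2)))
}

rlnorm_med_cv <- function(n, median, cv) {
  if (cv == 0) return(rep(median, n))
  p <- lnorm_pars(median, cv)
  stats::rlnorm(n, p$meanlog, p$sdlog)
}

# normal truncated below at `lower`, drawn by inverse-CDF so that sd = 0
# degenerates to the mean exactly
rtruncnorm_lower <- function(n, mean, sd, lower = 0) {
  if (sd == 0) return(rep(mean, n))
  p_lo <- stats::pnorm(lower, mean, sd)
  u <- stats::runif(n, p_lo, 1)
  stats::qnorm(u, mean, sd)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

is_count <- function(x) is.numeric(x) && length(x) == 1 && !is.na(x) &&
  x >= 0 && x == floor(x)

stop_if_not_scalar_pos <- function(x, name, allow_zero = FALSE) {
  ok <- is.numeric(x) && length(x) == 1 && is.finite(x) &&
    (x > 0 || (allow_zero && x >= 0))
  if (!ok) stop(sprintf("'%s' must be a %s finite number", name,
                        if (allow_zero) "nonnegative" else "strictly positive"),
                call. = FALSE)
  invisible(TRUE)
}
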