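#' Equal-width marker bin edges
#'
#' Default binning for landscape estimation: `n_bins` equal-width bins.
#' With `trim = c(0.01, 0.99)` (the package default for general use) the
#' bins span the 1st-99th percentile of the marker; `trim = c(0, 1)` spans
#' the full observed range, which keeps the highest-marker bags inside the
#' top bin.
#'
#' @param values marker values.
#' @param n_bins number of bins.
#' @param trim quantile range spanned by the bins.
#' @return numeric vector of `n_bins + 1` strictly increasing edges.
#' @export
default_bin_edges <- function(values, n_bins = 8, trim = c(0.01, 0.99)) {
  rng <- stats::quantile(values, trim, names = FALSE)
  if (diff(rng) <= 0) stop("degenerate marker range")
  seq(rng[1], rng[2], length.out = n_bins + 1)
}

#' Binned germination probability along a marker
#'
#' Per marker bin, the estimated germination probability is the fraction of
#' bags in the bin that germinated. Bins with fewer than `min_count` bags
#' are still reported but flagged unreliable; empty bins carry `NA`.
#'
#' @param records a `spore_bag_records` data frame.
#' @param marker column name of the marker (default GFP inducibility).
#' @param bin_edges strictly increasing bin edges.
#' @param min_count reliability threshold (default 5 bags).
#' @return data.frame with `bin_lo`, `bin_hi`, `bin_mid`, `prob`, `count`,
#'   `unreliable`.
#' @export
bin_probability <- function(records, marker = "gfp_inducibility_au",
                            bin_edges, min_count = 5) {
  if (any(diff(bin_edges) <= 0)) stop("bin_edges must be strictly increasing")
  values <- records[[marker]]
  if (is.null(values)) stop("unknown marker column: ", marker)
  if (any(!is.finite(values))) stop("marker values must be finite")
  n_bins <- length(bin_edges) - 1
  idx <- findInterval(values, bin_edges, rightmost.closed = TRUE)
  in_range <- idx >= 1 & idx <= n_bins
  counts <- tabulate(idx[in_range], nbins = n_bins)
  germ <- tabulate(idx[in_range & records$germinated], nbins = n_bins)
  prob <- ifelse(counts > 0, germ / counts, NA_real_)
  data.frame(bin_lo = bin_edges[-(n_bins + 1)],
             bin_hi = bin_edges[-1],
             bin_mid = (bin_edges[-1] + bin_edges[-(n_bins + 1)]) / 2,
             prob = prob, count = counts,
             unreliable = counts < min_count)
}

#' Estimate the germination landscape
#'
#' Germination probability over glucose concentration (rows) x marker bin
#' (columns), the single-cell "germination landscape". When a replicate
#' column is given, each pixel is either the mean of the per-replicate
#' probability estimates (`combine = "mean"`, mirroring per-population
#' averaging across replicate populations) or the pooled-count estimate
#' (`combine = "pool"`).
#'
#' @param records a `spore_bag_records` data frame covering the requested
#'   glucose levels.
#' @param marker marker column name.
#' @param bin_edges marker bin edges (default: [default_bin_edges()] on all
#'   records).
#' @param glucose_levels rows of the landscape (default: levels present).
#' @param replicate_col optional column naming replicate populations.
#' @param combine `"mean"` (default) or `"pool"`.
#' @param min_count per-bin reliability threshold.
#' @return object of class `landscape_grid`: list with `prob` and `counts`
#'   matrices (glucose x bin), `glucose_levels`, `bin_edges`, `marker`,
#'   `unreliable` flag matrix, and `replicates` per-pixel replicate counts.
#' @export
estimate_landscape <- function(records, marker = "gfp_inducibility_au",
                               bin_edges = NULL, glucose_levels = NULL,
                               replicate_col = NULL,
                               combine = c("mean", "pool"), min_count = 5) {
  combine <- match.arg(combine)
  if (is.null(bin_edges)) bin_edges <- default_bin_edges(records[[marker]])
  if (is.null(glucose_levels))
    glucose_levels <- sort(unique(records$glucose_pct))
  n_bins <- length(bin_edges) - 1
  prob <- counts <- reps <- matrix(NA_real_, length(glucose_levels), n_bins)
  for (g in seq_along(glucose_levels)) {
    sub <- records[records$glucose_pct == glucose_levels[g], , drop = FALSE]
    if (nrow(sub) == 0) { counts[g, ] <- 0; reps[g, ] <- 0; next }
    if (is.null(replicate_col) || combine == "pool") {
      bp <- bin_probability(sub, marker, bin_edges, min_count)
      prob[g, ] <- bp$prob
      counts[g, ] <- bp$count
      reps[g, ] <- as.numeric(bp$count > 0)
    } else {
      rep_ids <- unique(sub[[replicate_col]])
      mats <- lapply(rep_ids, function(r) {
        bin_probability(sub[sub[[replicate_col]] == r, , drop = FALSE],
                        marker, bin_edges, min_count)
      })
      pm <- sapply(mats, `[[`, "prob")
      cm <- sapply(mats, `[[`, "count")
      prob[g, ] <- rowMeans(pm, na.rm = TRUE)
      prob[g, is.nan(prob[g, ])] <- NA_real_
      counts[g, ] <- rowSums(cm)
      reps[g, ] <- rowSums(!is.na(pm))
    }
  }
  structure(list(prob = prob, counts = counts,
                 glucose_levels = glucose_levels, bin_edges = bin_edges,
                 marker = marker, unreliable = counts < min_count,
                 replicates = reps),
            class = "landscape_grid")
}

#' @export
print.landscape_grid <- function(x, ...) {
  cat(sprintf("<landscape_grid: %d glucose levels x %d %s bins>\n",
              length(x$glucose_levels), ncol(x$prob), x$marker))
  m <- round(x$prob, 3)
  dimnames(m) <- list(paste0(signif(x$glucose_levels, 3), "%"),
                      signif((x$bin_edges[-1] + x$bin_edges[-length(x$bin_edges)]) / 2, 3))
  print(m)
  invisible(x)
}

#' Fit a four-parameter logistic dose-response curve
#'
#' Weighted least-squares fit of
#' `f(c) = floor + (ceiling - floor) / (1 + (c50/c)^h)` on the
#' log10-glucose axis, the population-level sigmoidal step in germinated
#' fraction. The fit is initialized from the concentration bracketing the
#' midpoint between the observed floor and ceiling.
#'
#' @param fractions data.frame with columns `glucose_pct`, `fraction`, and
#'   optionally `weight`.
#' @return object of class `dose_response_fit`: `c50`, `hill_slope`,
#'   `floor_frac`, `ceiling_frac`, `fit_residual` (RMS), `covariance`.
#' @export
fit_dose_response <- function(fractions) {
  g <- fractions$glucose_pct
  f <- fractions$fraction
  w <- fractions$weight %||% rep(1, length(f))
  if (length(unique(g)) < 4)
    stop("need at least 4 distinct glucose levels")
  if (any(f < 0 | f > 1)) stop("fractions must lie in [0, 1]")
  if (diff(range(f)) < 1e-10)
    stop("all fractions equal: no dose-response transition to fit")
  lc <- log10(g)
  # initialize l50 from the concentrations bracketing the half-maximal level
  mid <- (min(f) + max(f)) / 2
  ord <- order(lc)
  above <- f[ord] >= mid
  i <- which(above)[1]
  l50_0 <- if (!is.na(i) && i > 1) (lc[ord][i] + lc[ord][i - 1]) / 2 else
    stats::median(lc)
  dat <- data.frame(lc = lc, f = f)
  fit <- tryCatch(
    minpack.lm::nlsLM(
      f ~ lo + (hi - lo) / (1 + 10^(h * (l50 - lc))),
      data = dat, weights = w,
      start = list(lo = max(min(f), 1e-3), hi = min(max(f), 1 - 1e-3),
                   l50 = l50_0, h = 2),
      lower = c(0, 0, min(lc) - 2, 0.05),
      upper = c(1, 1, max(lc) + 2, 50),
      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) stop("dose-response fit failed to converge: ",
                             conditionMessage(e), call. = FALSE))
  cf <- stats::coef(fit)
  res <- stats::resid(fit)
  structure(list(c50 = unname(10^cf["l50"]),
                 hill_slope = unname(cf["h"]),
                 floor_frac = unname(cf["lo"]),
                 ceiling_frac = unname(cf["hi"]),
                 fit_residual = sqrt(mean(res^2)),
                 covariance = stats::vcov(fit),
                 model = fit),
            class = "dose_response_fit")
}

#' @export
print.dose_response_fit <- function(x, ...) {
  cat(sprintf(paste0("dose-response fit: c50 = %.5f%% glucose, hill = %.2f, ",
                     "floor = %.3f, ceiling = %.3f (RMS residual %.4f)\n"),
              x$c50, x$hill_slope, x$floor_frac, x$ceiling_frac,
              x$fit_residual))
  invisible(x)
}

#' Minimum glucose concentration for near-certain germination
#'
#' Within one marker bin, fits a binomial logistic regression of the
#' germination outcome on log10(glucose) and inverts it at `target_p`
#' (default 0.99): the minimum glucose concentration at which a bag of
#' this marker level has a `target_p` chance of germinating. Returns a
#' flag: `"interpolated"` within the tested range, `"extrapolated"`
#' beyond it, `"lower_bound"` when every bag germinated (the true minimum
#' lies at or below the smallest tested concentration), `"separation"`
#' when outcomes are perfectly separated along glucose (the boundary is
#' reported, not a fitted value).
#'
#' @param records data.frame with `glucose_pct` and `germinated` for the
#'   bags of one marker bin, spanning >= 3 glucose levels.
#' @param target_p target germination probability.
#' @return list with `glucose_pct`, `flag`, and (when fitted) `model`.
#' @export
min_glucose_for_germination <- function(records, target_p = 0.99) {
  g <- records$glucose_pct
  y <- records$germinated
  if (length(unique(g)) < 3) stop("need >= 3 glucose levels in the bin")
  if (all(y)) return(list(glucose_pct = min(g), flag = "lower_bound"))
  if (!any(y)) stop("no germination in bin: all probabilities below target")
  # perfect separation: every non-germinated bag at lower glucose than every
  # germinated one
  if (max(g[!y]) < min(g[y])) {
    boundary <- sqrt(max(g[!y]) * min(g[y]))  # log-midpoint
    return(list(glucose_pct = boundary, flag = "separation"))
  }
  fit <- suppressWarnings(stats::glm(y ~ log10(g), family = stats::binomial()))
  b <- stats::coef(fit)
  if (!is.finite(b[2]) || b[2] <= 0)
    stop("fitted germination probability is not increasing in glucose")
  lc <- (stats::qlogis(target_p) - b[1]) / b[2]
  conc <- unname(10^lc)
  flag <- if (conc > max(g) || conc < min(g)) "extrapolated" else "interpolated"
  list(glucose_pct = conc, flag = flag, model = fit)
}

#' Pearson association between two single-spore markers
#'
#' Pearson correlation with its two-sided p-value plus the ordinary
#' least-squares regression line, as used for marker-marker association
#' panels (e.g. RNAP II level vs GFP inducibility).
#'
#' @param x,y numeric vectors of equal length, n >= 3, nonconstant.
#' @return object of class `association_result`: `pearson_r`, `p_value`,
#'   `slope`, `intercept`, `n`.
#' @export
pearson_association <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 3) stop("need at least 3 observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("correlation undefined for constant input")
  ct <- stats::cor.test(x, y, method = "pearson")
  fit <- stats::lm(y ~ x)
  structure(list(pearson_r = unname(ct$estimate),
                 p_value = ct$p.value,
                 slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 n = length(x)),
            class = "association_result")
}

#' @export
print.association_result <- function(x, ...) {
  cat(sprintf("association: R = %.3f (P = %.3g, n = %d), y = %.3g + %.3g x\n",
              x$pearson_r, x$p_value, x$n, x$intercept, x$slope))
  invisible(x)
}
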