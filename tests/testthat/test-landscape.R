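test_that("bin_probability matches hand enumeration and flags sparse bins", {
  rec <- records_df(marker = c(1, 1, 2, 2, 3, 3),
                    germinated = c(TRUE, FALSE, TRUE, TRUE, FALSE, FALSE))
  bp <- bin_probability(rec, bin_edges = c(0.5, 1.5, 2.5, 3.5))
  expect_equal(bp$prob, c(0.5, 1.0, 0.0))
  expect_equal(bp$count, c(2L, 2L, 2L))
  expect_true(all(bp$unreliable))  # all below the default min_count of 5

  all_germ <- records_df(rep(1:3, each = 4), rep(TRUE, 12))
  bp2 <- bin_probability(all_germ, bin_edges = c(0.5, 1.5, 2.5, 3.5))
  expect_equal(bp2$prob, rep(1, 3))

  expect_error(bin_probability(rec, bin_edges = c(1, 1, 2)), "increasing")
  empty <- bin_probability(records_df(numeric(), logical()),
                           bin_edges = c(0, 1, 2))
  expect_true(all(is.na(empty$prob)))
})

test_that("estimate_landscape reduces to bin_probability and averages replicates", {
  cfg <- generator_config(n_bags = 400, glucose_levels = 0.003)
  rec <- generate_population(cfg, seed = 8)
  edges <- default_bin_edges(rec$gfp_inducibility_au)
  grid <- estimate_landscape(rec, bin_edges = edges)
  bp <- bin_probability(rec, bin_edges = edges)
  expect_equal(unname(grid$prob[1, ]), bp$prob)
  expect_equal(unname(grid$counts[1, ]), as.numeric(bp$count))

  # replicate averaging: pixel = mean of the three per-replicate estimates
  rec$replicate <- rep(1:3, length.out = nrow(rec))
  grid_m <- estimate_landscape(rec, bin_edges = edges,
                               replicate_col = "replicate")
  manual <- sapply(1:3, function(r)
    bin_probability(rec[rec$replicate == r, ], bin_edges = edges)$prob)
  expect_equal(unname(grid_m$prob[1, ]), rowMeans(manual, na.rm = TRUE),
               tolerance = 1e-12)

  # counts row-sum equals records falling inside the binned range
  inside <- sum(rec$gfp_inducibility_au >= edges[1] &
                  rec$gfp_inducibility_au <= edges[length(edges)])
  expect_equal(sum(grid$counts[1, ]), inside)
})

test_that("a monotone generative landscape is recovered monotonically at n = 10,000", {
  cfg <- generator_config(n_bags = 10000,
                          glucose_levels = c(0.001, 0.002, 0.004, 0.008))
  rec <- generate_population(cfg, seed = 13)
  edges <- default_bin_edges(rec$gfp_inducibility_au, n_bins = 8)
  grid <- estimate_landscape(rec, bin_edges = edges)
  # isotonic projection along each axis changes estimates by less than
  # sampling noise
  iso_change <- function(v) {
    ok <- !is.na(v)
    if (sum(ok) < 3) return(0)
    mean(abs(stats::isoreg(seq_along(v[ok]), v[ok])$yf - v[ok]))
  }
  row_viol <- apply(grid$prob, 1, iso_change)  # increasing in marker
  col_viol <- apply(grid$prob, 2, iso_change)  # increasing in glucose
  expect_lt(max(row_viol, col_viol), 0.02)
})

test_that("dose-response fit recovers exact logistic parameters", {
  gluc <- 10^seq(-3.7, 0.3, length.out = 8)
  truth <- list(lo = 0.1, hi = 1.0, c50 = 0.003, h = 1.5)
  f <- truth$lo + (truth$hi - truth$lo) /
    (1 + (truth$c50 / gluc)^truth$h)
  fit <- fit_dose_response(data.frame(glucose_pct = gluc, fraction = f))
  expect_equal(fit$c50, truth$c50, tolerance = 1e-6)
  expect_equal(fit$hill_slope, truth$h, tolerance = 1e-6)
  expect_equal(fit$floor_frac, truth$lo, tolerance = 1e-6)
  expect_equal(fit$ceiling_frac, truth$hi, tolerance = 1e-6)

  # symmetric logistic: fitted value at c50 is the floor/ceiling midpoint
  pred <- fit$floor_frac + (fit$ceiling_frac - fit$floor_frac) / 2
  f_at_c50 <- truth$lo + (truth$hi - truth$lo) / 2
  expect_equal(pred, f_at_c50, tolerance = 1e-6)

  expect_error(fit_dose_response(data.frame(glucose_pct = gluc[1:3],
                                            fraction = f[1:3])),
               "4 distinct")
  expect_error(fit_dose_response(data.frame(glucose_pct = gluc,
                                            fraction = rep(0.5, 8))),
               "no dose-response transition")
})

test_that("dose-response c50 estimate is unbiased over replicate seeds", {
  cfg <- generator_config(n_bags = 150)
  c50s <- vapply(1:25, function(seed) {
    rec <- generate_population(cfg, seed = seed)
    frac <- stats::aggregate(germinated ~ glucose_pct, rec, mean)
    names(frac)[2] <- "fraction"
    fit_dose_response(frac)$c50
  }, numeric(1))
  expect_lt(abs(mean(c50s) - 0.003), 0.0005)
})

test_that("minimum glucose for 99% germination inverts the generative logistic", {
  # outcomes drawn from a known logistic in log10(glucose)
  set.seed(21)
  a <- 9; b <- 3.2  # p = plogis(a + b log10 c); p = 0.99 at log10 c = (qlogis(.99)-a)/b
  gluc <- rep(10^seq(-4, 0, length.out = 9), each = 300)
  y <- rbinom(length(gluc), 1, plogis(a + b * log10(gluc))) == 1
  res <- min_glucose_for_germination(data.frame(glucose_pct = gluc,
                                                germinated = y))
  analytic <- 10^((qlogis(0.99) - a) / b)
  expect_equal(res$glucose_pct, analytic, tolerance = 0.15)
  expect_equal(res$flag, "interpolated")

  # saturated bin: lower-bound flag at the smallest tested concentration
  sat <- min_glucose_for_germination(
    data.frame(glucose_pct = gluc, germinated = TRUE))
  expect_equal(sat$flag, "lower_bound")
  expect_equal(sat$glucose_pct, min(gluc))

  # perfect separation reports the boundary, not a fitted value
  sep <- min_glucose_for_germination(
    data.frame(glucose_pct = rep(c(0.001, 0.01, 0.1), each = 5),
               germinated = rep(c(FALSE, TRUE, TRUE), each = 5)))
  expect_equal(sep$flag, "separation")
  expect_equal(sep$glucose_pct, sqrt(0.001 * 0.01))
})

test_that("lower-capacity bins need strictly more glucose to guarantee germination", {
  cfg <- generator_config(n_bags = 4000,
                          glucose_levels = 10^seq(-3.5, -1.5, length.out = 7))
  rec <- generate_population(cfg, seed = 17)
  med <- stats::median(rec$gfp_inducibility_au)
  lo <- rec[rec$gfp_inducibility_au < med * 0.8, ]
  hi <- rec[rec$gfp_inducibility_au > med * 1.3, ]
  g_lo <- min_glucose_for_germination(lo)$glucose_pct
  g_hi <- min_glucose_for_germination(hi)$glucose_pct
  expect_gt(g_lo, g_hi)
})

test_that("pearson_association matches the textbook formula", {
  tab <- data.frame(x = c(1, 2, 3, 4), y = c(2, 1, 4, 3))
  res <- pearson_association(tab$x, tab$y)
  expect_equal(res$pearson_r, 0.6)  # hand: cov 1, sd_x sd_y = 5/3
  expect_equal(res$n, 4L)

  perfect <- pearson_association(1:10, 2 * (1:10) + 1)
  expect_equal(perfect$pearson_r, 1.0)
  expect_equal(perfect$slope, 2.0)
  expect_equal(perfect$intercept, 1.0)

  expect_error(pearson_association(rep(1, 5), 1:5), "constant")
  expect_error(pearson_association(1:2, 1:2), "at least 3")
})

test_that("generator hits a target marker correlation at the sample size of the data", {
  cfg <- generator_config(n_bags = 182, glucose_levels = 2)
  rs <- vapply(1:20, function(seed) {
    rec <- generate_population(cfg, seed = seed)
    pearson_association(rec$capacity_true, rec$rnap2_level_au)$pearson_r
  }, numeric(1))
  # sampling CI of r = 0.64 at n = 182 is about +/- 0.09
  expect_lt(abs(mean(rs) - 0.64), 0.05)
})
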