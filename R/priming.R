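#' Priming statistics: mean germination delay and relative delta-tau
#'
#' Delta-tau is the mean time taken to germinate after a glucose step-up;
#' the relative delta-tau divides the primed cohort's mean by that of a
#' control cohort that saw no first glucose. A seeded bootstrap supplies a
#' percentile confidence interval for the ratio.
#'
#' @param primed_times germination times (minutes) of the primed cohort.
#' @param control_times germination times (minutes) of the no-first-glucose
#'   control cohort.
#' @param n_boot bootstrap resamples (default 2000).
#' @param conf confidence level.
#' @param seed seed for the bootstrap.
#' @return object of class `priming_result`: `delta_tau_min`,
#'   `relative_delta_tau`, `ci`, `n_primed`, `n_control`.
#' @export
relative_delta_tau <- function(primed_times, control_times, n_boot = 2000,
                               conf = 0.95, seed = 1L) {
  if (!length(primed_times) || !length(control_times))
    stop("both cohorts must be non-empty")
  if (any(primed_times <= 0) || any(control_times <= 0))
    stop("germination times must be positive")
  m_ctrl <- mean(control_times)
  if (m_ctrl == 0) stop("control mean is zero")
  delta_tau <- mean(primed_times)
  rel <- delta_tau / m_ctrl
  set.seed(as.integer(seed))
  boot <- vapply(seq_len(n_boot), function(i) {
    mean(sample(primed_times, replace = TRUE)) /
      mean(sample(control_times, replace = TRUE))
  }, numeric(1))
  alpha <- (1 - conf) / 2
  ci <- unname(stats::quantile(boot, c(alpha, 1 - alpha)))
  structure(list(delta_tau_min = delta_tau, relative_delta_tau = rel,
                 ci = ci, n_primed = length(primed_times),
                 n_control = length(control_times)),
            class = "priming_result")
}

#' @export
print.priming_result <- function(x, ...) {
  cat(sprintf(paste0("priming: delta-tau = %.1f min, relative delta-tau = ",
                     "%.3f [%.3f, %.3f] (n = %d primed, %d control)\n"),
              x$delta_tau_min, x$relative_delta_tau, x$ci[1], x$ci[2],
              x$n_primed, x$n_control))
  invisible(x)
}

#' Transcriptional-module normalized-expression ratio table
#'
#' For each gene, the expression level at every timepoint is divided by its
#' own 0-hour level; these normalized levels are averaged over the genes of
#' each transcriptional module; and the primed module average is divided by
#' the unprimed module average. The 0-hour column is identically 1 by
#' construction. Genes with a zero 0-hour level in either table are
#' excluded (their count is reported in the `dropped_genes` attribute);
#' modules left without genes carry an `NA` row and are listed in the
#' `flagged_modules` attribute. Normalization makes the result invariant
#' to per-gene multiplicative scaling.
#'
#' @param expr_primed,expr_unprimed gene x timepoint matrices with
#'   identical row (gene) and column (timepoint) names.
#' @param module_map data.frame with columns `gene` and `module`.
#' @param average `"arithmetic"` (default) or `"geometric"` module
#'   averaging of normalized levels.
#' @return matrix of class `module_ratio_table` (modules x timepoints).
#' @export
module_expression_ratio <- function(expr_primed, expr_unprimed, module_map,
                                    average = c("arithmetic", "geometric")) {
  average <- match.arg(average)
  if (!identical(dim(expr_primed), dim(expr_unprimed)) ||
      !identical(rownames(expr_primed), rownames(expr_unprimed)) ||
      !identical(colnames(expr_primed), colnames(expr_unprimed)))
    stop("primed and unprimed tables must share genes and timepoints")
  if (is.null(rownames(expr_primed))) stop("tables must carry gene rownames")

  zero_base <- expr_primed[, 1] <= 0 | expr_unprimed[, 1] <= 0
  n_dropped <- sum(zero_base)
  if (n_dropped > 0)
    warning(n_dropped, " gene(s) with zero 0-h expression excluded")
  ep <- expr_primed[!zero_base, , drop = FALSE]
  eu <- expr_unprimed[!zero_base, , drop = FALSE]
  norm_p <- ep / ep[, 1]
  norm_u <- eu / eu[, 1]

  modules <- unique(module_map$module)
  agg <- function(m, mat) {
    genes <- intersect(module_map$gene[module_map$module == m], rownames(mat))
    if (!length(genes)) return(rep(NA_real_, ncol(mat)))
    sub <- mat[genes, , drop = FALSE]
    if (average == "arithmetic") colMeans(sub)
    else exp(colMeans(log(sub)))
  }
  ratio <- t(vapply(modules, function(m) agg(m, norm_p) / agg(m, norm_u),
                    numeric(ncol(ep))))
  dimnames(ratio) <- list(modules, colnames(ep))
  flagged <- modules[apply(ratio, 1, function(r) all(is.na(r)))]
  structure(ratio, dropped_genes = n_dropped, flagged_modules = flagged,
            class = c("module_ratio_table", "matrix", "array"))
}
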