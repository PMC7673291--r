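#' Pipeline configuration
#'
#' @param output_dir directory for stage outputs (created if absent).
#' @param stages character subset of
#'   `c("generate", "landscape", "kinetics", "deathmodel", "priming")`;
#'   stages run in that order.
#' @param generator a [generator_config()].
#' @param seed master seed; stage seeds are derived by fixed offsets so
#'   each stage's dataset is independently reproducible.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(output_dir,
                            stages = c("generate", "landscape", "kinetics",
                                       "deathmodel", "priming"),
                            generator = generator_config(),
                            seed = 1L) {
  known <- c("generate", "landscape", "kinetics", "deathmodel", "priming")
  if (length(setdiff(stages, known)))
    stop("unknown stage(s): ", paste(setdiff(stages, known), collapse = ", "))
  structure(list(output_dir = output_dir, stages = stages,
                 generator = validate_generator_config(generator),
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

stage_seed <- function(config, offset) config$seed * 1000L + offset

#' Run the analysis pipeline
#'
#' Executes the toggled stages (generate -> landscape -> kinetics ->
#' deathmodel -> priming) on synthetic data and writes their outputs under
#' `output_dir`, plus a `manifest.json` recording the seed, package and R
#' versions, and an MD5 checksum of every artifact, so that a rerun with
#' the same configuration reproduces identical outputs.
#'
#' @param config a [pipeline_config()].
#' @return the manifest (list), invisibly.
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "pipeline_config")) stop("invalid pipeline config")
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  out <- function(f) file.path(config$output_dir, f)
  gen <- config$generator
  files <- character()

  if ("generate" %in% config$stages || "landscape" %in% config$stages) {
    records <- generate_population(gen, seed = stage_seed(config, 1L))
    write_records(records, out("records.csv"))
    files <- c(files, "records.csv")
  }
  if ("landscape" %in% config$stages) {
    grid <- estimate_landscape(records)
    write_landscape(grid, out("landscape.tsv"), out("landscape.json"))
    frac <- stats::aggregate(germinated ~ glucose_pct, records, mean)
    names(frac) <- c("glucose_pct", "fraction")
    frac$weight <- as.numeric(table(records$glucose_pct))
    dr <- fit_dose_response(frac)
    jsonlite::write_json(list(c50_pct = dr$c50, hill_slope = dr$hill_slope,
                              floor_frac = dr$floor_frac,
                              ceiling_frac = dr$ceiling_frac),
                         out("dose_response.json"), auto_unbox = TRUE,
                         digits = NA)
    files <- c(files, "landscape.tsv", "landscape.json", "dose_response.json")
  }
  if ("kinetics" %in% config$stages) {
    aged <- generate_ageing_series(gen, c(0, 30), seed = stage_seed(config, 2L))
    traces <- generate_traces(aged[["30"]], gen, seed = stage_seed(config, 3L))
    fits <- lapply(traces, fit_trace_exponential)
    fit_df <- data.frame(
      bag_id = vapply(traces, `[[`, character(1), "bag_id"),
      rate_per_h = vapply(fits, `[[`, numeric(1), "rate_per_h"),
      lag_h = vapply(fits, `[[`, numeric(1), "lag_h"),
      r2 = vapply(fits, `[[`, numeric(1), "r2"),
      classification = vapply(fits, `[[`, character(1), "classification"))
    utils::write.csv(fit_df, out("trace_fits.csv"), row.names = FALSE, na = "")
    rates <- decompose_production(gen$ageing$degradation_halflife_days,
                                  gen$ageing$net_halflife_days)
    jsonlite::write_json(unclass(rates)[1:4], out("kinetic_rates.json"),
                         auto_unbox = TRUE, digits = NA)
    files <- c(files, "trace_fits.csv", "kinetic_rates.json")
  }
  if ("deathmodel" %in% config$stages) {
    sim <- simulate_population(default_death_model(seed = stage_seed(config, 4L)),
                               seq(0, 80, by = 4))
    utils::write.csv(sim$survival, out("survival.csv"), row.names = FALSE)
    files <- c(files, "survival.csv")
  }
  if ("priming" %in% config$stages) {
    pr <- generate_priming_dataset(gen, seed = stage_seed(config, 5L))
    stats_pr <- relative_delta_tau(pr$primed_times, pr$unprimed_times,
                                   seed = stage_seed(config, 6L))
    jsonlite::write_json(list(delta_tau_min = stats_pr$delta_tau_min,
                              relative_delta_tau = stats_pr$relative_delta_tau,
                              ci = stats_pr$ci),
                         out("priming.json"), auto_unbox = TRUE, digits = NA)
    ratio <- module_expression_ratio(pr$expr_primed, pr$expr_unprimed,
                                     pr$module_map)
    utils::write.table(cbind(module = rownames(ratio), as.data.frame(ratio)),
                       out("module_ratio.tsv"), sep = "\t",
                       row.names = FALSE, quote = FALSE)
    files <- c(files, "priming.json", "module_ratio.tsv")
  }

  manifest <- list(
    seed = config$seed,
    stages = config$stages,
    package_version = as.character(utils::packageVersion("sporedormancy")),
    r_version = R.version.string,
    outputs = lapply(stats::setNames(files, files), function(f)
      list(file = f, md5 = unname(tools::md5sum(out(f))))))
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(manifest)
}
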