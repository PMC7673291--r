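# Readers and writers for the package's plain-text formats. Units are
# embedded in column names (minutes for germination, hours for traces,
# days for ageing) to keep files unambiguous.

RECORD_MANDATORY_COLS <- c("bag_id", "glucose_pct", "germinated",
                           "germination_time_min", "gfp_inducibility_au",
                           "rnap2_level_au", "age_days", "condition")
RECORD_NUMERIC_COLS <- c("glucose_pct", "germination_time_min",
                         "gfp_inducibility_au", "rnap2_level_au",
                         "age_days", "capacity_true", "rrna_level_au",
                         "total_rna_rate_au")

#' Write spore-bag records to CSV
#'
#' One row per spore bag; comma-separated, UTF-8, '.' decimal, header
#' mandatory.
#'
#' @param records a `spore_bag_records` data frame.
#' @param path output file.
#' @return the path, invisibly.
#' @export
write_records <- function(records, path) {
  utils::write.csv(as.data.frame(records), path, row.names = FALSE,
                   na = "")
  invisible(path)
}

#' Read spore-bag records from CSV
#'
#' Validates the documented schema: mandatory columns must be present
#' (schema error naming the first missing column otherwise) and numeric
#' columns must parse (row-level error with the row index otherwise).
#' Unknown columns are preserved.
#'
#' @param path CSV file with header.
#' @return a `spore_bag_records` data frame.
#' @export
read_records <- function(path) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character")
  missing_cols <- setdiff(RECORD_MANDATORY_COLS, names(raw))
  if (length(missing_cols))
    stop("schema error: missing mandatory column '", missing_cols[1], "'")
  if (nrow(raw) == 0) {
    out <- empty_records(generator_config(n_bags = 0))
    return(out[, intersect(names(out), names(raw)), drop = FALSE])
  }
  for (col in intersect(RECORD_NUMERIC_COLS, names(raw))) {
    vals <- raw[[col]]
    num <- suppressWarnings(as.numeric(vals))
    bad <- which(is.na(num) & !(is.na(vals) | vals == ""))
    if (length(bad))
      stop("unparseable numeric in column '", col, "' at row ", bad[1])
    raw[[col]] <- num
  }
  for (col in intersect(c("germinated", "primed", "dead"), names(raw)))
    raw[[col]] <- as.logical(raw[[col]])
  class(raw) <- c("spore_bag_records", "data.frame")
  raw
}

#' Write traces as long-format CSV
#'
#' Columns: `bag_id`, `time_h`, `fluor_au`, `baseline_au`,
#' `germination_time_h`.
#'
#' @param traces list of [trace_series()].
#' @param path output file.
#' @return the path, invisibly.
#' @export
write_traces <- function(traces, path) {
  long <- do.call(rbind, lapply(traces, function(tr) {
    data.frame(bag_id = tr$bag_id, time_h = tr$times_h,
               fluor_au = tr$fluor_au, baseline_au = tr$baseline_au,
               germination_time_h = tr$germination_time_h,
               stringsAsFactors = FALSE)
  }))
  utils::write.csv(long, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Read traces from long-format CSV
#'
#' @param path CSV written by [write_traces()].
#' @return list of [trace_series()].
#' @export
read_traces <- function(path) {
  long <- utils::read.csv(path, stringsAsFactors = FALSE)
  lapply(split(long, long$bag_id), function(d) {
    d <- d[order(d$time_h), ]
    trace_series(bag_id = d$bag_id[1], times_h = d$time_h,
                 fluor_au = d$fluor_au, baseline_au = d$baseline_au[1],
                 germination_time_h = d$germination_time_h[1])
  })
}

#' Write a landscape grid as TSV plus JSON sidecar
#'
#' The TSV holds the probability matrix (rows: glucose levels, columns:
#' marker bin midpoints); the sidecar records bin edges, per-pixel counts,
#' reliability flags and the marker name.
#'
#' @param grid a `landscape_grid`.
#' @param path_tsv,path_json output files.
#' @return `path_tsv`, invisibly.
#' @export
write_landscape <- function(grid, path_tsv, path_json) {
  m <- grid$prob
  mids <- (grid$bin_edges[-1] + grid$bin_edges[-length(grid$bin_edges)]) / 2
  df <- data.frame(glucose_pct = grid$glucose_levels, m)
  names(df) <- c("glucose_pct", paste0("bin_", signif(mids, 4)))
  utils::write.table(df, path_tsv, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  jsonlite::write_json(
    list(marker = grid$marker, bin_edges = grid$bin_edges,
         glucose_levels = grid$glucose_levels, counts = grid$counts,
         unreliable = grid$unreliable, replicates = grid$replicates),
    path_json, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path_tsv)
}

#' Write a generator configuration as YAML or JSON
#'
#' Format follows the file extension: `.yaml`/`.yml` or `.json`.
#'
#' @param config a [generator_config()].
#' @param path output file.
#' @return the path, invisibly.
#' @export
write_generator_config <- function(config, path) {
  validate_generator_config(config)
  if (grepl("\\.json$", path)) {
    jsonlite::write_json(unclass(config), path, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE, null = "null")
  } else {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("the 'yaml' package is required for YAML output")
    yaml::write_yaml(unclass(config), path)
  }
  invisible(path)
}

#' Read a generator configuration from YAML or JSON
#'
#' Fields absent from the file fall back to the package defaults; the
#' result is validated.
#'
#' @param path file written by [write_generator_config()] (or hand-edited).
#' @return a [generator_config()].
#' @export
read_generator_config <- function(path) {
  raw <- if (grepl("\\.json$", path)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("the 'yaml' package is required for YAML input")
    yaml::read_yaml(path)
  }
  config <- generator_config()
  as_dbl <- function(v) if (is.integer(v)) as.numeric(v) else v
  for (nm in names(raw)) {
    if (is.list(config[[nm]]) && is.list(raw[[nm]])) {
      for (sub in names(raw[[nm]]))
        config[[nm]][[sub]] <- as_dbl(raw[[nm]][[sub]])
    } else {
      config[[nm]] <- as_dbl(raw[[nm]])
    }
  }
  config$seed <- as.integer(config$seed)
  validate_generator_config(config)
}
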