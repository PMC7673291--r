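#!/usr/bin/env Rscript
## Generate the synthetic datasets used by the downstream analysis scripts:
## a multi-concentration spore-bag population, ageing series (no drug and
## cycloheximide), post-glucose fluorescence traces for an aged population,
## and a two-step-glucose priming dataset. All downstream scripts read from
## results/data/.

suppressPackageStartupMessages(library(sporedormancy))

out <- file.path("results", "data")
dir.create(out, showWarnings = FALSE, recursive = TRUE)
cfg <- generator_config(n_bags = 150)
seed <- 20L

records <- generate_population(cfg, seed = seed)
write_records(records, file.path(out, "population.csv"))
message(sprintf("population: %d bags x %d glucose levels, %.0f%% germinated at 2%%",
                cfg$n_bags, length(cfg$glucose_levels),
                100 * mean(records$germinated[records$glucose_pct == 2])))

for (cond in c("none", "cycloheximide")) {
  series <- generate_ageing_series(cfg, seq(0, 28, by = 2), seed = seed + 1,
                                   condition = cond)
  aged <- do.call(rbind, series)
  write_records(aged, file.path(out, paste0("ageing_", cond, ".csv")))
}
message("ageing series written for no-drug and cycloheximide conditions")

# traces for a 30-day-old population: survivors are dormant, the rest dead
aged30 <- generate_ageing_series(cfg, 30, seed = seed + 2)[["30"]]
traces <- generate_traces(aged30, cfg, seed = seed + 3)
write_traces(traces, file.path(out, "traces_day30.csv"))
write_records(aged30, file.path(out, "population_day30.csv"))
message(sprintf("traces: %d bags (%d dead at day 30)", nrow(aged30),
                sum(aged30$dead)))

pr <- generate_priming_dataset(cfg, delay_h = 16, seed = seed + 4)
utils::write.csv(data.frame(cohort = rep(c("primed", "unprimed"),
                                         each = cfg$n_bags),
                            germination_time_min = c(pr$primed_times,
                                                     pr$unprimed_times)),
                 file.path(out, "priming_times.csv"), row.names = FALSE)
utils::write.csv(data.frame(gene = rownames(pr$expr_primed), pr$expr_primed,
                            check.names = FALSE),
                 file.path(out, "expression_primed.csv"), row.names = FALSE)
utils::write.csv(data.frame(gene = rownames(pr$expr_unprimed), pr$expr_unprimed,
                            check.names = FALSE),
                 file.path(out, "expression_unprimed.csv"), row.names = FALSE)
utils::write.csv(pr$module_map, file.path(out, "module_map.csv"),
                 row.names = FALSE)
message("priming dataset written")
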