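# sporedormancy

Quantifying how budding-yeast spores age and die during dormancy, from
single-spore-bag measurements.

Not every genetically identical spore germinates when given glucose. The
fraction that does rises as a sharp sigmoid of the glucose concentration,
and whether an individual spore bag germinates is predicted by its
gene-expressing capacity (GFP inducibility, RNA polymerase II level).
During dormancy those expression-enabling molecules are degraded faster
than they are produced; when a spore's pool falls below a threshold the
spore has irreversibly lost the ability to express genes — it is dead.
This package implements that analysis chain for researchers working on
microbial dormancy and single-cell dose–response data:

* **Germination landscape** — binned Bernoulli estimation of
  P(germinate | marker bin, glucose), with replicate averaging
  (`bin_probability()`, `estimate_landscape()`).
* **Dose–response** — weighted 4-parameter logistic fit on log10-glucose,
  `f(c) = floor + (ceiling − floor)/(1 + (c50/c)^h)`, and the inverse
  logistic-regression estimate of the minimum glucose giving a 99%
  germination chance (`fit_dose_response()`,
  `min_glucose_for_germination()`).
* **Trace kinetics** — lag detection and exponential production-rate fits
  to per-spore fluorescence traces, `fold(t) = exp(k (t − lag))`,
  classifying producing vs non-producing spores
  (`detect_lag()`, `fit_trace_exponential()`).
* **Turnover decomposition** — half-lives by first-crossing linear
  interpolation and the perturbation decomposition
  `k_deg = ln2/t½(CHX)`, `k_net = ln2/t½(no drug)`,
  `production = k_deg − k_net` (`half_life_by_interpolation()`,
  `decompose_production()`).
* **Threshold-death simulator** — per-spore molecular pools
  `M(t) = p/d + (M0 − p/d)e^(−dt)` with death at the first threshold
  crossing by any species, under drug schedules that rescale production
  (`death_time_closed_form()`, `simulate_population()`).
* **Priming statistics** — Δτ and relative Δτ with bootstrap CIs, and
  0-h-normalized transcriptional-module expression ratios
  (`relative_delta_tau()`, `module_expression_ratio()`).
* **Synthetic-data generator** — lognormal capacity heterogeneity, a
  logistic-in-log-glucose germination landscape with capacity-dependent
  c50, exponential ageing, drug effects, and noisy post-glucose traces,
  so the whole pipeline runs and is tested without any raw microscopy
  (`generator_config()`, `generate_population()`, `generate_traces()`,
  `generate_ageing_series()`, `generate_priming_dataset()`).

## Worked example

```r
library(sporedormancy)

# rate decomposition from the measured RNAP II half-lives:
# 8.4 days under cycloheximide, 14 days drug-free
decompose_production(8.4, 14)
#> kinetic rates: k_deg 0.0825/day, k_net 0.0495/day, production 0.0330/day
#>   (characteristic time 30.3 days) [ok]

# population dose-response on a synthetic population
cfg <- generator_config(n_bags = 150)
rec <- generate_population(cfg, seed = 21)
frac <- aggregate(germinated ~ glucose_pct, rec, mean)
names(frac)[2] <- "fraction"
fit_dose_response(frac)
#> dose-response fit: c50 = 0.00268% glucose, hill = 2.66, floor = 0.085,
#>   ceiling = 1.000 (RMS residual 0.0051)
```

A dormant spore produces RNAP II at ~0.033/day relative rate — one
characteristic production time of ~30 days, i.e. effectively no
replenishment against an 8.4-day degradation half-life. The fitted c50
says half the spore bags germinate at ~0.003% glucose, a 670-fold lower
concentration than the saturating 2%.

The numbered scripts under `analysis/` run the full chain on synthetic
data (generate → dose–response → landscape → trace kinetics → ageing
half-lives → death model → priming) and write their tables under
`results/`; each prints its headline numbers, e.g. dormancy half-lives of
~38 days (drug-free) vs ~23 days (cycloheximide), and 50% killing within
12 h of transcription inhibition while spores still hold ~97% of their
RNAP II.

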