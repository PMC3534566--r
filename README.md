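# fireclades

Dating the origin of fire-adapted traits and fireprone habitats on
time-calibrated phylogenies.

Many plant lineages in fire-prone vegetation carry seed syndromes whose only
known function is tied to fire: serotiny (canopy seed storage released by
fire heat), persistent soil seed banks with heat- or smoke-cued germination,
and ant-buried arillate seeds. `fireclades` implements, as one tested R
package, the inference chain needed to date such traits on a genus-level
chronogram and to ask whether entering fireprone habitats accelerated
diversification:

* **Trait models** — binary-trait continuous-time Markov (Mk) models and
  4-state trait-pair models, with pruning-algorithm likelihoods and seeded
  forward simulation (`mk_model()`, `pair_model()`, `prune_log_likelihood()`,
  `simulate_trait()`).
* **Bayesian engine** — Metropolis–Hastings / reversible-jump MCMC over rate
  parameters with an exponential prior seeded by a uniform(0, 30) hyperprior,
  automatic tuning of the proposal step to a 20–40% acceptance rate, node-state
  sampling, and harmonic-mean marginal likelihoods
  (`run_chain()`, `tune_ratedev()`, `harmonic_mean_logL()`).
* **Correlated evolution** — Pagel-style dependent (8-rate) vs independent
  (4-rate) model comparison; the log-Bayes factor
  `2 * (log HM_dep − log HM_indep)` is referred to a χ² critical value
  (9.49 at df = 4, α = 0.05) (`test_correlation()`, `bf_critical_value()`).
* **Habitat biogeography** — a two-area dispersal–extinction–cladogenesis
  (DEC) model over ranges {F, N, FN} with unconstrained dispersal, ML fitting,
  ancestral-range probabilities and dispersal-event detection (`fit_dec()`),
  plus the habitat-as-trait alternative (`habitat_as_trait()`).
* **Node assignment and dating** — corrected posterior probabilities
  (node trait posterior × clade support, threshold 0.95), stem propagation,
  trait-origin dating and lineages-through-time tallies at 10-My intervals
  (`assign_nodes()`, `date_origin()`, `lineage_timeline()`).
* **Diversification** — stem-group net speciation rates `R_st = log(N)/t`
  and sister-clade rate ratios at habitat-divergence events
  (`stem_rate()`, `find_divergence_events()`, `rate_ratio_summary()`).
* **Synthetic data** — seeded simulators for chronograms (including
  habitat-linked birth rates), traits, ranges, and a complete
  "family-scale" fixture bundle with a planted fireprone radiation
  (`simulate_tree()`, `make_fixture()`).

## Worked example

```r
library(fireclades)

dir <- tempfile()
make_fixture(dir, seed = 4242)       # 80-tip, 113-My synthetic bundle

cfg <- pipeline_config(
  tree = file.path(dir, "tree.nwk"),
  traits = file.path(dir, "traits.tsv"),
  ranges = file.path(dir, "ranges.tsv"),
  species_counts = file.path(dir, "species_counts.tsv"),
  out_dir = file.path(dir, "out"), seed = 7)
res <- run_pipeline(cfg, quiet = TRUE)

res$origins$habitat
#> origin of habitat: 75.58 Ma at stem of node 87
res$origins$soil_storage
#> origin of soil_storage: 75.58 Ma at stem of node 87
res$events[, c("event", "age", "N_fire", "N_nonfire", "ratio")]
#>   event      age N_fire N_nonfire    ratio
#> 1    D1 75.58095    779        32 1.921096
res$correlations[[2]]
#> correlated evolution soil_storage ~ habitat: log-BF = 12.63 (df = 4, critical 9.49) -> correlated
#>   harmonic-mean MC SE of the log-BF ~ 1.16 (estimator is high-variance)
```

Reading: the fireprone radiation planted in the fixture is recovered as a
single divergence event `D1` at 75.6 Ma — the true planted stem age, which
is also where the fireprone habitat and the soil-storage trait are dated to
originate. The fireprone side of that split carries 779 species against 32
in its sister, a net speciation ratio of 1.9, and soil seed storage tests
as correlated with fireprone habitat, with a log-Bayes factor above the
9.49 decision threshold. Per-node assignment tables, the habitat timeline,
and a human-readable `report.txt` are written under `out_dir`.

A thin command-line wrapper with `simulate` and `run` subcommands is
installed at `inst/cli/fireclades.R`.

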