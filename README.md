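# tcpalm

Time-correlated PALM (tcPALM) analysis of transient protein clusters in R.

Single-molecule localization movies of photoconvertible fusions (e.g.
Dendra2–RPB1 for RNA polymerase II) record one detection per fluorophore per
frame. When molecules assemble transiently — as Pol II does in promoter
clusters — the detections inside a spatial region arrive in a concentrated
temporal burst whose duration reflects the cluster's lifetime, while fixed
(chemically immobilized) controls accumulate detections steadily across the
whole movie through blinking alone. `tcpalm` implements the full analysis
chain that turns a localization table into per-cluster lifetimes and
between-condition statistics, for microscopists and quantitative biologists
working with ThunderSTORM-style localization data:

1. **Spatial clustering** — density-based (DBSCAN) detection of clusters
   from raw localizations, with the conventional small (< 200 nm) / large
   (> 200 nm) diameter classification.
2. **Temporal burst segmentation** — detections of one cluster are merged
   across dark gaps of up to a blinking cutoff (default 100 frames);
   larger gaps split the stream into separate bursts.
3. **Cumulative-trace fitting** — each burst's cumulative detection count
   N(t) is fitted by a Gaussian-CDF sigmoid with a bounded linear
   background,

   N(t) = A Φ((t − t₀)/w) + b (t − t_first),

   and the correlation time (lifetime) is the 10–90% rise time of the
   sigmoid, τ = 2 × 1.28155 × w, with goodness-of-fit R².
4. **Gating ledger** — R² ≥ 0.98 gate, burst-count normalization across
   conditions (default 2500), a modal-frequency filter (bins below 20% of
   the modal histogram bin are dropped), and the live/fixed discrimination
   rule (τ < 20 s is live-like). Every gate's drop count is recorded.
5. **Statistics** — per-condition summaries (median ± MAD and mean ± SEM,
   always labelled), empirical cumulative lifetime distributions, and the
   unpaired two-sided Wilcoxon rank-sum test between conditions.

Because raw imaging data of this kind is rarely depositable at analysis
scale, the package ships a **synthetic localization generator** with ground
truth: live-cell fields of transient clusters with known ON-windows and
Dendra2-like geometric blinking, and fixed-cell photophysics-only controls.
Every downstream stage is validated against this truth in the test suite.

## Worked example

```r
library(tcpalm)

acq   <- acquisition_params()                       # 10,000 frames x 10 ms = 100 s
specs <- live_cluster_specs(n_clusters = 10, acq = acq, seed = 42)
tbl   <- simulate_live_cell(acq, live_photophysics(), specs,
                            background_rate_hz = 50, seed = 42)

clusters <- detect_spatial_clusters(tbl)
fits     <- fit_cluster_lifetimes(tbl, clusters)
set      <- apply_all_gates(fits, filter_config(), condition = "WT")
summarize_lifetimes(set)
```

which prints

```
# A tibble: 1 × 7
  condition n_clusters median_tau_s mad_s mean_tau_s  sd_s sem_s
  <chr>          <int>        <dbl> <dbl>      <dbl> <dbl> <dbl>
1 WT                 9         6.77  3.01       6.90  2.75 0.917
```

Nine of the twelve fitted bursts survive the gates (three fail the
R² ≥ 0.98 gate — `lifetime_provenance(set)` itemizes the drops), and the
gated median lifetime of 6.77 s sits where it should for clusters whose
simulated ON-windows were drawn uniformly between 4 and 12 s. A fitted
burst can be inspected with `autoplot()` on its `cdf_fit`, and a gated set
with `plot_lifetime_histogram()` / `plot_lifetime_ecdf()`. Two-condition
comparisons run end-to-end through `run_tcpalm_pipeline()`; see the
methods vignette (`vignettes/tcpalm-methods.Rmd`) for the model, parameter
and design discussion.

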