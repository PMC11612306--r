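---
title: "tcPALM cluster-lifetime analysis: models, parameters, and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{tcPALM cluster-lifetime analysis: models, parameters, and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tcpalm)
```

## The measurement and the model

Time-correlated PALM asks a temporal question of spatial data: within one
spatial cluster of single-molecule detections, how are the detections
distributed in time? A transient protein cluster (RNA Pol II at an active
promoter is the motivating case) recruits many photoconvertible fusion
molecules during a finite ON-window, so its detections pile up in a
concentrated rise; an immobile molecule in a fixed cell produces detections
at a steady blinking-limited rate across the whole movie. The analysis
chain is:

1. spatial clusters from the localization table (DBSCAN);
2. per-cluster temporal bursts, merging dark gaps up to a blinking cutoff;
3. a least-squares fit of each burst's cumulative detection count;
4. a gating ledger on the fitted correlation times;
5. per-condition summaries and rank-sum comparisons.

### The cumulative-trace model

For a burst with detections at times $t_1 \le \dots \le t_n$ (seconds from
acquisition start; detections sharing a frame are collapsed into one step),
the cumulative count $N(t)$ is fitted by

$$N(t) = A\,\Phi\!\left(\frac{t - t_0}{w}\right) + b\,(t - t_1),$$

where $\Phi$ is the standard Gaussian CDF, $A$ the detection amplitude,
$t_0$ the half-rise time, $w$ the rise scale, and $b$ a linear background
rate. The reported correlation time is the 10–90% rise time of the sigmoid,

$$\tau = 2\,\Phi^{-1}(0.9)\,w = 2 \times 1.28155 \times w,$$

so a width of exactly 1 s maps to $\tau = 2.5631$ s. $R^2$ is computed as
$1 - SS_{res}/SS_{tot}$ over the trace points. We chose a Gaussian-CDF
sigmoid because it is the smoothest two-parameter rise with a closed-form
map between its width and a quantile-based rise time; nothing downstream
depends on this particular sigmoid family, and the raw burst span
(`raw_span_s`, last minus first detection time) is always emitted alongside
$\tau$ so the two lifetime notions can be compared.

### Identifiability of the fit

An unconstrained linear background is collinear with arbitrarily wide
sigmoids: a constant-rate trace is fitted *exactly* by $b$ alone for any
$(t_0, w)$, making $\tau$ meaningless, and the sigmoid's far tail can
mimic a ramp with absurd $(A, t_0)$. The fit therefore imposes box bounds
that encode how the traces are constructed:

* $0 \le b \le 0.2\,n/(t_n - t_1)$ — background inside a sub-200-nm region
  of interest is sparse relative to cluster emission, so the linear term
  may absorb at most 20% of the gross detection rate;
* $t_1 \le t_0 \le t_n$ — a burst is fully observed (it ends when the
  detections end), so the half-rise lies inside the data;
* $0 < A \le 1.5\,n$ and $10^{-6} \le w \le 2\,(t_n - t_1)$.

With these bounds a constant-rate trace is fitted by a sigmoid of width
$\approx 0.3 \times$ span, i.e. $\tau \approx 0.77 \times$ span — which is
exactly the behavior that separates fixed-cell traces (span ≈ the whole
100-s movie, $\tau \gg 20$ s) from live clusters (span ≈ the ON-window,
$\tau < 20$ s).

### Numerical choices

The fit is deterministic: Levenberg–Marquardt (`minpack.lm::nlsLM`,
`ftol = ptol = 1e-13`, 500 iterations) from a single start derived from the
empirical trace ($t_0$ = time of median count, $w$ = empirical 10–90%
spread / 2.5631, $A = n$, $b = 0$), followed by a bounded L-BFGS-B polish
(`factr = 10`) that settles the very shallow SSE valley along $w$; there
are no random restarts. Degenerate inputs are handled explicitly: a trace
whose detections all fall in one frame is the exact zero-width step limit
($w = \tau = 0$, $R^2 = 1$ since residual and total sums of squares both
vanish); bursts with fewer than `min_burst_detections` detections return a
typed `tcpalm_insufficient` object rather than an error; negative $R^2$
(fit worse than the mean) is clamped to 0.

Boundary conventions, each chosen once: a dark gap exactly equal to the
blinking cutoff still merges (the cutoff is the largest gap attributable to
blinking); a diameter exactly at the 200-nm threshold classifies *large*
(the conventional strict inequalities leave the boundary unassigned); a
correlation time exactly at 20 s classifies *fixed-like* (the live rule is
strictly below); the $R^2$ gate is inclusive at its threshold.

## Tunable parameters

| Parameter | Default | Units | Why |
|---|---|---|---|
| `n_frames` | 10,000 | frames | standard tcPALM acquisition |
| `frame_time_s` | 0.01 | s | 10-ms exposure; total 100 s |
| `field_size_nm` | 20,000 | nm | a nuclear field of view |
| `localization_sigma_nm` | 15 | nm | typical SMLM precision |
| `neighborhood_radius_nm` | 50 | nm | DBSCAN linking distance |
| `min_localizations` | 10 | counts | core-point / reporting threshold |
| `size_threshold_nm` | 200 | nm | small/large cluster boundary |
| `blinking_cutoff_frames` | 100 | frames | shorter cutoffs leave too few usable bursts for a reliable cumulative fit |
| `min_burst_detections` | 10 | counts | below this a fit is not attempted |
| `r2_min` | 0.98 | – | goodness-of-fit gate |
| `n_bursts_norm` | 2500 | counts | burst-count normalization across conditions |
| `freq_fraction` | 0.20 | – | modal-frequency filter threshold |
| `hist_bin_width_s` | 2 | s | frequency-filter histogram bin |
| `live_tau_max_s` | 20 | s | live/fixed discrimination bound |

The frequency-filter bin width is not canonical anywhere; 2 s resolves the
3–10-s live regime without emptying bins at realistic cluster counts. The
filter is applied per condition (pooling conditions would let a large
condition dictate another's modal bin).

## The gating ledger

Gates run in the order $R^2$ → burst-count subsampling → modal-frequency
filter → live/fixed rule, and the per-gate drop counts (`provenance`)
always sum, with the retained count, to the input size, so alternative
orders can be audited. Two deliberate choices:

* **"2500 bursts" as a common target.** Subsampling to `n_bursts_norm` is
  read as equalizing burst counts across compared conditions; when every
  condition has fewer, the pipeline uses the smallest per-condition
  post-$R^2$ count for all of them, so no condition is ever upsampled.
  Subsampling is seeded (`subsample_seed`) and order-preserving.
* **Labelling before dropping.** The live/fixed rule labels every gated
  value (`class` column); dropping a class is opt-in
  (`class_filter = "live_like"` when comparing live-cell conditions). This
  keeps the composition of a gated set observable — the fraction of
  fixed-like values in a live-cell condition is itself a useful
  photophysics diagnostic — and the drop, when requested, is still recorded
  in the provenance.

Applying the ledger twice changes nothing (idempotence), and the modal
histogram bin can never be removed by the frequency filter.

## What the synthetic generator emulates — and what it does not

The live-cell generator places transient clusters (Gaussian molecule
positions of sigma `radius_nm` around a center) with finite ON-windows;
molecules are recruited at times uniform over the window, blink in
geometric burst/dark trains (memoryless — the simplest model consistent
with fluorophore blinking), bleach after a geometric number of bursts, and
every detection adds Gaussian localization error. Background is uniform in
space and time. The fixed-cell generator is the photophysics-only control:
immobile emitters blinking over the whole movie with effectively negligible
bleaching, whose dark gaps (mean 10 frames) stay far below the 100-frame
cutoff so each emitter yields one movie-spanning burst.

Preset calibration, chosen once as a realistic regime: 10 live clusters of
sigma 60 nm with lifetimes uniform on 4–12 s and 30 molecules each
(3 bursts of ~3 frames per molecule at 100 Hz in-burst detection),
50 Hz field background; 200 fixed molecules. Uniform recruitment makes the
cumulative trace an approximately linear ramp over the ON-window, the
cleanest test signal for the CDF fit; the resulting gated lifetime medians
fall in the 5–10 s range live Pol II clusters occupy, and fixed-cell
correlation times land near 70–100 s, far above the 20-s bound.

Not emulated: stage drift, z-dimension and astigmatic PSF effects,
multi-channel imaging, non-uniform nuclear background, cluster movement,
non-exponential dark-state kinetics, and recruitment kinetics other than
uniform. Passing tests therefore demonstrate that the pipeline recovers
known temporal structure from blinking-corrupted point streams — not that
it is robust to drift or dense-emitter artifacts, which upstream
localization software must handle.

Two practical consequences of the preset geometry are worth knowing. With
sigma = 60 nm and ~300 detections, the maximum-pairwise-distance diameter
of a simulated cluster is typically ~300 nm (extremes of a Gaussian grow
with the sample count), so the default presets exercise the machinery
rather than the small/large taxonomy; tests of the size classifier use
tighter (20 nm) and wider (120 nm) clusters instead. And DBSCAN at a 50-nm
linking radius can split a few peripheral molecules off a sigma-60-nm
cluster; such fragments fit poorly ($R^2 < 0.98$) and are removed by the
gate, which is the same role the gate plays on real data. Cluster-recovery
tests therefore match detected to true clusters by majority membership
rather than by raw counts.

## Statistics

Summaries report median ± MAD *and* mean ± SEM, always labelled — a bare
"±" is ambiguous between the two. The two-condition comparison is the
unpaired two-sided Wilcoxon rank-sum test: exact enumeration when the
pooled sample is ≤ 20 and tie-free, normal approximation with tie and
continuity correction otherwise; p-values are kept at machine precision
and only rounded for display. The empirical cumulative distribution is
right-continuous with final value exactly 1.

## Problem sizes used by the test suite

The suite validates against independent oracles at sizes chosen to make
failures interpretable: exact agreement of burst segmentation with a
brute-force splitter on 1,000 random frame lists (cutoffs 1–200); fitted
correlation times within 15% of a 120 × 120 dense-grid least-squares
oracle on 20 simulated 8-s clusters; live/fixed discrimination fractions
pooled over 20 replicate simulated fields per condition; Wilcoxon
agreement with exhaustive rank enumeration for all sample-size splits of
pooled n ≤ 10 and a 500-replicate null-size check at n = 40 vs 45. The
full suite runs in a few minutes on one CPU.

## Known limitations

* The fitted $\tau$ of a single realization is noisy: with ~30 recruited
  molecules, two clusters with identical true 8-s windows can yield fitted
  lifetimes differing by a factor of two. Condition comparisons should rest
  on dozens of clusters, as the rank-sum test assumes.
* Whether the "lifetime" of a cluster is the fitted rise time or the raw
  burst span is a modeling choice; both are reported, and they agree to
  within ~25% on ramp-like traces.
* The fit is per temporal burst, not per whole-ROI trace; a cluster
  re-assembling after more than the blinking cutoff contributes several
  lifetimes.
* Diameter is the maximum pairwise member distance — sensitive to single
  outlier detections and to member count; 2 × RMS radius would be a
  stabler (smaller) alternative and would shift the small/large boundary
  correspondingly.
```{r session, echo = FALSE}
sessionInfo()
```
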