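---
title: "Methods: simulating and phenotyping intrinsic electrophysiological types"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and phenotyping intrinsic electrophysiological types}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(patchtype)
```

# Scope

`patchtype` reproduces, end to end, the analysis workflow used to sort
current-clamped neurons into four intrinsic electrophysiological phenotypes —
Type I (voltage sag, no rebound burst), Type II (rebound burst), Type III
(neither), and a low-excitability "Others" class — and to validate that
rule-based sort against unsupervised hierarchical clustering and group
statistics. Because raw recordings cannot ship with a source package, the
package includes a conductance-based simulator whose four parameter templates
emit voltage traces with the qualitative signatures of the four types; every
downstream stage (feature extraction, exclusion, classification, clustering,
ANOVA/Tukey) operates on plain data frames of sweeps and would work unchanged
on imported recordings with the same columns.

This vignette documents the model, the default parameters, what the generator
does and does not emulate, the measurement conventions, and the numerical
choices. All problem sizes used in examples and tests (cohort sizes, numbers
of Monte-Carlo replicates) are this package's own choices, picked to keep a
full run within a few minutes on one CPU.

# The neuron model

Each simulated neuron is a single compartment with capacitance $C_m$ (pF),
membrane voltage $V$ (mV), currents in pA and conductances in nS, integrated
in milliseconds:

$$C_m \frac{dV}{dt} = -I_L - I_h - I_T - I_D - w + I_{inj} + I_{noise}$$

with

* **Leak** $I_L = g_L (V - E_L)$.
* **H-current** $I_h = g_h\, m_h (V - E_h)$, one first-order gate
  $\tau_h \dot m_h = m_{h,\infty}(V) - m_h$ with a sigmoid steady state
  $m_{h,\infty}(V) = 1/(1+\exp((V - V_{1/2})/k))$ activating on
  hyperpolarization. This current produces both the depolarizing sag during
  hyperpolarizing steps and (with the T-current) rebound depolarization at
  step offset.
* **Low-threshold calcium-like current**
  $I_T = g_T\, m_{T,\infty}(V)\, h_T (V - E_T)$ with instantaneous
  activation and a slow inactivation gate $h_T$ (time constant
  `tau_th_gate`, 100 ms). De-inactivated by hyperpolarization, it drives
  the post-inhibitory rebound burst that defines Type II.
* **Slowly inactivating K⁺ D-type current**
  $I_D = g_D\, a_{D,\infty}(V)\, b_D (V - E_K)$ with instantaneous
  activation and very slow inactivation $b_D$ (`tau_db`, 2 s). A large
  $g_D$ delays the first spike by hundreds of milliseconds and clamps
  excitability at small current steps — the mechanism behind the "Others"
  phenotype (silent below +30 pA, at most one late spike near rheobase).
* **Spike emission.** Spikes are threshold events rather than simulated Na⁺/K⁺
  transients: when $V$ crosses an adaptive threshold $\theta$, a spike time is
  recorded, $V$ resets to `v_reset` for a refractory period `t_ref`, the
  adaptation current $w$ increments by `b_w` (decay `tau_w`) and $\theta$
  increments by `d_theta` (decay `tau_theta` toward `theta0`). In the sampled
  output trace each spike is painted as a +40 mV peak at its emission time so
  that downstream peak-based spike detection sees realistic waveforms.
* **Depolarization block.** Real neurons stop emitting full spikes when
  driven into sustained depolarization. The model low-pass filters $V$
  (time constant `tau_filt` = 5 ms) and suppresses spike emission while the
  filtered voltage exceeds `v_block`; the membrane then sits at a
  depolarized plateau, which the analysis side detects as block.

Gates use exponential-Euler updates; $V$ uses forward Euler with
`dt = 0.05` ms, downsampled to `dt_out = 0.1` ms (10 kHz, a typical
digitizer rate). Halving `dt` changes extracted features by far less than
the between-neuron jitter, so 0.05 ms is kept as the default for speed. The
integrator is implemented in C++ (via Rcpp) because an interpreted loop over
24 000 steps × 32 sweeps × 120 neurons would dominate the run time.

# Protocols

Three standard step protocols, all from a holding potential of −60 mV
(maintained by a constant bias current solved from the steady-state I–V
relation):

| Protocol | Mode | Steps | Duration | Onset |
|---|---|---|---|---|
| `excitability` | current clamp | −80 … +60 pA by 10 | 500 ms | 100 ms |
| `ih` | voltage clamp | −150 … −60 mV by 10 | 800 ms | 100 ms |
| `mfr` | current clamp | +50 … +750 pA by 50 | 1000 ms | 100 ms |

Step windows are half-open, `[onset, onset + duration)`. A separate
unclamped "rmp" trace (no bias) measures the resting membrane potential.
`protocol_spec()` lets users define their own protocols;
`match_protocol()` reassigns unlabeled imported sweeps to protocol steps by
their command waveform.

# Feature definitions

All measurements are window averages or peak statistics on the sampled
trace; spike times are peaks of threshold crossings (0 mV criterion, peaks
closer than 2 ms merged to the taller one).

* **Sag** (at −80 pA): steady-state voltage (mean of the last 100 ms of the
  step) minus the peak hyperpolarization (minimum over the first 150 ms of
  the step), clipped at zero. A ≥ 3 mV sag is the Type I criterion; the
  threshold is a package decision standing in for the by-eye judgement made
  at the rig, and is exposed as `sag_threshold`.
* **Rebound spikes** (after −80 pA): spikes in `(offset, offset + 500 ms]`.
  Any rebound spike ⇒ Type II.
* **I_h amplitude** (at −140 mV clamp): |steady current (last 50 ms of the
  step) − instantaneous current (10–30 ms after onset)|; the instantaneous
  window deliberately skips the capacitive transient. Density divides by
  capacitance (pA/pF).
* **Maximum firing rate**: per MFR sweep, spikes before depolarization-block
  onset; block onset is the first time the 5-ms low-passed trace stays above
  −20 mV for ≥ 50 ms without a spike. `mfr` is the maximum count over steps
  and `mfr_step` its current, ties resolved to the lowest step.
* **First-spike latency** (at +10 pA) and **first ISI** (at +40 pA): from
  step onset to first spike peak, and between the first two spike peaks.
* **ISI histograms**: 5 ms bins, counts normalized by the per-type sample
  size so types of different prevalence are comparable.
* **Passive properties**: RMP is the mean of the settled resting trace;
  input resistance is the through-origin regression of steady-state
  deflection on injected current over the −30/−20/−10 pA steps;
  the membrane time constant comes from an exponential fit to the charging
  transient (nonlinear least squares, with a log-linear fallback for
  noiseless traces where `nls` cannot start); capacitance is $\tau/R_{in}$.

# Classification rules

Applied in fixed order to each neuron (`classify_neurons()`):

1. **Excluded**: RMP more positive than −50 mV (strict; exactly −50 mV is
   kept) or no spikes at any depolarizing excitability step.
2. **Others**: silent at all excitability steps below +30 pA *and* at most
   one evoked spike at any step.
3. **Type II**: ≥ 1 rebound spike after the −80 pA step. Rebound precedes
   the sag rule because rebound spiking is treated as exclusive to Type II;
   a rebound neuron without sag is still Type II and is flagged in the
   per-neuron `rationale` string.
4. **Type I**: sag ≥ 3 mV at −80 pA.
5. **Type III**: otherwise.

`report_proportions()` formats published-style per-type counts as
percentages of the classified total.

# The four templates

`phenotype_template()` returns the per-type parameter sets. The type-defining
choices, in brief:

* **Type I**: moderate $g_h$ (1.6 nS) with a half-activation of −85 mV, so
  the −80 pA step produces a clear ≥ 3 mV sag but offset rebound stays
  subthreshold; no T-current.
* **Type II**: T-current ($g_T$ = 4 nS) plus modest $g_h$; the −80 pA step
  de-inactivates $h_T$ and the offset rebound fires a burst. The template
  also has the highest input resistance, hence the steepest evoked-spike
  response at small steps, the shortest first-spike latency and the lowest
  depolarization-block current (~200 pA).
* **Type III**: essentially leak-only ($g_h$ = 0.05 nS): no sag, no
  rebound, tonic firing that blocks near +500 pA.
* **Others**: large D-current ($g_D$ = 8 nS) over a hyperpolarized rest;
  silent below +30 pA and at most one late spike near rheobase; largest
  capacitance and the largest I_h *density* despite showing no sag, because
  its $g_h$ half-activates at −110 mV — substantially active at the
  −140 mV clamp but barely recruited at the −80 pA current step. It never
  reaches depolarization block within the +750 pA range.

`make_cohort()` jitters the conductances and capacitance log-normally
(default 10 %) and the leak reversal by a small Gaussian, and assigns each
neuron a rostro-caudal position from a fixed anatomical grid. Template
parameters were tuned until each template robustly expresses its defining
qualitative signature under jitter; they are not fits to any particular
recorded cell.

What the generator does **not** emulate: conductance-based Na⁺/K⁺ spike
shapes, channel noise and stochastic firing irregularity, electrode/access
artifacts, temperature or liquid-junction effects, and any synaptic input.
Recorded data will therefore show broader feature distributions than a
simulated cohort at default jitter.

# Clustering

Two standardized parameter sets mirror common practice:

* **three**: I_h density at −140 mV, sag at −80 pA, rebound spikes at
  −80 pA — the type-defining trio, all cells except Excluded;
* **six**: the three above plus `mfr_step`, first-spike latency at +10 pA
  and first ISI at +40 pA, with "Others" removed a priori (their missing
  latency/ISI values would otherwise silently shrink the sample).

Rows with any missing value are dropped and reported via the `dropped`
attribute. Columns are z-scored by default (`standardize()`); the features
mix mV, pA/pF, counts and ms, so unscaled Euclidean distance would be
dominated by `mfr_step`.

`ward_linkage()` implements Ward's minimum-variance agglomeration in the
`ward.D2` convention directly on the data matrix: at each step it merges the
pair of clusters with the smallest increase in within-cluster sum of squares
$\Delta SS = \frac{n_i n_j}{n_i+n_j}\lVert c_i - c_j\rVert^2$, recording
height $\sqrt{2\,\Delta SS}$; ties go to the pair created earliest. The
merge sequence itself is the scientific object here (the dendrogram and its
cuts), so the package computes it explicitly and cross-checks it in the test
suite both against `stats::hclust(method = "ward.D2")` heights and against
an exhaustive oracle that recomputes every candidate merge cost from the raw
members. The returned object is `hclust`-compatible, so `cutree()`,
`ape::as.phylo()` and plotting all work; `cut_clusters()` and
`cluster_agreement()` quantify how well a k-cut recovers the rule-based
labels (per-cluster majority purity and overall agreement). Exports:
Newick dendrogram, leaf-ordered heatmap TSV, and a raw-valued 3-D scatter
table (evoked spikes at +60 pA × rebound × sag).

# Statistics

Group comparisons use the standard linear-model machinery rather than
re-implementations: `two_way_anova()` fits `lm` with sum-to-zero contrasts
and reports Type-III tests via `car::Anova()` (the design — type × current
step — is unbalanced after exclusion, so Type III is the appropriate
partition); `one_way_anova()` wraps `aov`; `tukey_hsd()` wraps
`TukeyHSD()`, and `tukey_by_step()` runs one Tukey family per current step
so that multiplicity correction happens within each step's family, matching
how per-step post-hoc comparisons are usually reported. The test suite
verifies Tukey adjusted p-values against a direct studentized-range
(`ptukey`) computation and checks the empirical size of the interaction
test on null data. `summarize_groups()` returns mean ± SEM with n, SEM
being `NA` for singleton groups rather than 0.

All model outputs have `tidy()`/`glance()` methods so they drop into
data-frame workflows.

# Input/output

Traces are exchanged as a directory of `traces.csv` plus a `manifest.json`
declaring schema version, and per-protocol mode and units; readers reject
unknown schema versions, undeclared protocols and unit mismatches rather
than guessing. Numeric columns are written with 17 significant digits and
parsed with base R so that a write/read round trip is bit-exact — a
property the test suite asserts, and one that common fast CSV readers do
not guarantee. Feature tables use TSV with explicit `NA`.

# Reproducibility

`run_pipeline(run_config(seed = ...))` executes the whole chain
deterministically from one seed and records a manifest (seed, package
version, config hash, per-stage row counts). `inst/scripts/run_pipeline.R`
exposes it on the command line, and `scripts/acceptance.R` recomputes the
package's headline quantities (classification proportions, classifier
recovery, clustering purity, oracle agreements, fixture errors, test
calibration) into a flat JSON file.

# Limitations

* Spikes are threshold events: spike *shape* features (width,
  after-hyperpolarization, threshold voltage from dV/dt) are out of scope.
* The depolarization-block rule is phenomenological; block current
  thresholds are template properties, not predictions from channel kinetics.
* The 3 mV sag criterion and the −50 mV exclusion cutoff are fixed
  operating points for a judgement that is partly visual in practice; both
  are exposed as arguments.
* Simulated cohorts are cleaner than recordings; classifier recovery and
  cluster purity measured on them are upper bounds, not estimates of
  performance on experimental data.
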