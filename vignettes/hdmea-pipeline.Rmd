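---
title: "From raw HD-MEA traces to burst-initiation maps: the meaburst pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From raw HD-MEA traces to burst-initiation maps: the meaburst pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(meaburst)
```

# The problem

High-density microelectrode arrays (HD-MEAs) record extracellular voltage
from thousands of electrodes at 20 kHz. In co-cultures of dorsal root
ganglion (DRG, sensory) and spinal neurons, optogenetic pulses delivered to
the sensory side drive activity into the spinal network; the scientific
questions are cellular (which spinal neurons become active, and by how
much?) and network-level (how do synchronous population bursts, and the
neurons that initiate them, change during and after stimulation?).

`meaburst` implements the full computational chain for such sessions:

1. **Preprocessing** — per-electrode spike extraction from raw traces;
2. **Sorting** — grouping spikes into putative single neurons ("waveform
   clusters") within 9-electrode recording units;
3. **Burst analysis** — network-burst detection, initiation-point
   attribution, propagation order;
4. **Activity metrics** — per-period firing rates, normalized change,
   presence patterns, burst-frequency fold change, collective activity
   strength, pairwise synchrony, and paired nonparametric tests;
5. **Colocalization** — the point-based marker count used to verify
   culture separation;
6. **Synthetic sessions** — a generator producing raw traces with full
   ground truth, so every stage is testable without laboratory data.

Since raw laboratory recordings are not redistributable, the synthetic
generator is a first-class module: it defines the conditions under which
the pipeline's correctness claims are made.

# Session structure and conventions

A session consists of three periods — 20 min of spontaneous activity,
30 min with optical stimulation (5 ms pulses at 0.2 Hz), 20 min of
follow-up — sampled at 20 kHz. Electrodes are grouped into 3×3 recording
units of nine electrodes; a unit is the scope within which spikes are
sorted. Durations scale freely (tests use 2/3/2-min sessions); all rules
are duration-agnostic.

# Preprocessing

**Filtering.** A 4th-order Butterworth bandpass (100–3000 Hz) is applied
forward and backward, giving zero net phase. Zero phase matters because
burst-initiation attribution ranks clusters by spike time: a causal filter
would delay peaks by a frequency-dependent amount. The forward–backward
pass is computed in compiled code with odd-reflection padding; design
measurements on the default band: a biphasic spike template passes at ~98%
amplitude with no peak shift, white noise is attenuated to 0.51× its raw
SD, and a voltage step rings for roughly ±1 ms.

**Thresholding.** The noise SD of each electrode is estimated robustly as
`median(|x − median(x)|)/0.6745` — the median absolute deviation scaled to
be consistent for Gaussian noise, so sparse spikes barely inflate it — and
the detection level is the trace mean minus 5 estimated SDs. A degenerate
MAD of zero (constant or clipped traces) flags the electrode as skipped:
the threshold would collapse to the mean and detect everything.

**Detection.** Spikes are reported at local minima below the level; within
any 2 ms only the first detection is kept (greedy, restarting from each
kept spike), reflecting the neuronal refractory period. Detections within
a closed window from 1 ms before each stimulation pulse to 1 ms after it
are discarded: the stimulation artifact's switching edges produce spurious
threshold crossings exactly there.

# Sorting

Within each unit, the electrode with the most detections is the
*representative electrode*; 41-sample (2 ms) windows centred on its spike
times are cut from all nine filtered traces and concatenated into
369-dimensional feature vectors. These are embedded in 2-D with UMAP
(20 nearest neighbours, minimum distance 0.2) and clustered with DBSCAN
(5 minimum samples); clusters of 50 or fewer spikes are discarded.

Numerical choices worth knowing:

* **Sub-sample alignment.** The detected minimum sits on the sample grid;
  when the continuous peak falls between two samples, noise flips the
  argmin between them and splits one neuron's waveforms into two alignment
  families (observed: 7/20 single-neuron units split on a test session).
  `sort_unit()` therefore aligns each window to the fractional peak of the
  representative electrode (parabolic interpolation, linear resampling).
  Windows are still centred on the detected spike time.
* **DBSCAN radius.** When `eps = "auto"`, the radius is taken at the knee
  of the ascending sorted curve of each point's 5th-nearest-neighbour
  distance. The knee is located by maximum deviation below the chord
  joining the curve's endpoints. A maximum-second-difference rule was
  evaluated and rejected: a single tight clump (e.g. a few near-identical
  artifact waveforms) creates an early kink that captures eps at the clump
  scale and relegates the real clusters to noise.
* **No DBSCAN library is declared**: density clustering is implemented in
  the package (closed eps-balls, neighbourhood counts include the point
  itself) because none is available in the supported dependency set.
* **Determinism.** UMAP is stochastic; the embedding seed is fixed by the
  session seed and the optimiser runs single-threaded, so identical seeds
  give identical labels.
* Units with fewer waveforms than the UMAP neighbourhood (21) are reported
  unsortable; over-merged clusters are not split post hoc.

# Burst analysis

A network burst exists wherever a 100 ms window holds strictly more than
50 spikes of the pooled raster of all retained clusters; overlapping
qualifying windows are merged, and the burst spans its first to last
contained spike. The criterion is applied to the pooled raster because a
network burst is the simultaneous activation of many neurons; a
per-cluster mode (the same rule on one train) is available via
`burst_params(mode = "per-cluster")`.

The *initiator* of a burst is the cluster owning the earliest spike at or
after burst onset (ties to the lowest cluster id); mapping initiators to
their units yields the initiation-point map per period. Clusters
initiating fewer than 3 bursts are dropped from the initiator table.
Propagation order ranks participants by first post-onset spike, compared
across bursts by Spearman rank correlation over shared clusters.

**Limitation — onset under background spiking.** Burst onset is formalized
as the first spike of the merged qualifying region. Any background spike
falling at most ~half a window before the true leading edge can anchor a
qualifying window and become the onset, stealing the attribution. With a
dense population (e.g. 110 clusters at 0.5 Hz ⇒ 55 Hz pooled) most bursts
are therefore attributed to a background spike rather than the leader;
attribution is reliable when background inside burst windows is sparse.
The initiator-recovery checks are accordingly run on sessions without
background and with contamination injected only inside bursts. A
rate-based onset estimator would relax this, but is outside the pipeline's
formalized scope.

# Activity metrics

* **Rates** are spike counts over period durations.
* **Normalized change** between a pre-rate `a` and a later rate `b` is
  `(b − a)/(b + a)`: 1 for newly active clusters, 0 for unchanged, −1 for
  silenced, undefined when both are 0. Among bounded forms this is the one
  that pins "newly active" to exactly 1 and "unchanged" to exactly 0.
* **Presence patterns** classify each cluster by the periods in which it
  has at least one spike (e.g. `011` = absent before stimulation).
* **Burst-frequency fold change** is the per-minute burst rate relative to
  the pre-period; a zero pre-rate yields a flagged infinite fold rather
  than a dropped sample.
* **Collective activity strength** is the per-burst percentage of retained
  clusters with at least one spike inside the burst, averaged per period —
  a formalization chosen here, as the quantity is conventionally reported
  in percent without a published formula.
* **Synchrony** bins each cluster's train (default 100 ms, matching the
  burst window scale; configurable) and averages the Pearson correlation
  over all pairs with nonzero variance, reporting stimulation and
  follow-up values relative to baseline in percent.
* **Paired comparisons** use the two-sided Wilcoxon signed-rank test: an
  exact null computed by the shift algorithm over doubled midranks for
  fewer than 20 nonzero pairs (correct under ties, where the textbook
  exact tables do not apply), the tie-corrected normal approximation
  otherwise; Bonferroni correction multiplies by the number of
  comparisons, capped at 1.

# Colocalization

Given nucleus and marker point sets (µm coordinates), each marker claims
its nearest nucleus within 10 µm (ties by input order) and claimed nuclei
are de-duplicated, so several nuclei crowding one marker count once. The
marker-positive fraction is claimed nuclei over all nuclei. Image
processing (peak finding) is out of scope; inputs are coordinate lists.

# The synthetic generator and what passing tests mean

`simulate_session()` produces raw traces plus ground truth. Defaults are
fixed at the study conditions the pipeline targets:

| parameter | default | meaning |
|---|---|---|
| periods | 20/30/20 min | pre / stimulation / post |
| pulse train | 5 ms at 0.2 Hz | optical stimulation |
| units | 110 (3×3 electrodes, 17.5 µm pitch) | recording units |
| baseline rate | 0.5 Hz | spontaneous spinal firing |
| inactive fraction | 0.38 | neurons silent before stimulation |
| burst rates | 0.5 / 6 / 4 per min | programmed folds 12× and 8× |
| participation | 0.45 / 0.30 / 0.35 | per-burst recruitment of the population |
| propagation delay | 5 ms | inter-neuron lag inside bursts |
| within-burst spikes | 6 at 3 ms | per participating neuron |
| spike amplitude | 50–120 µV on 6 µV noise | SNR ≥ 8 |
| artifact | 30 µV ramp + steps | see below |
| refractory | 2.5 ms | enforced in generated trains |

Neurons silent before stimulation switch to the baseline rate at
stimulation onset and stay active — emulating recruitment that persists
after stimulation ends. Burst leaders are drawn one from the pre-active
population and the rest from the inactive set, so initiation points
multiply during stimulation. Each burst recruits members in a fixed
per-leader spatial order with the leader first by at least the propagation
delay.

The **artifact** is modelled as a linear ramp across each pulse with step
discontinuities at both edges and alternating polarity — the minimal shape
consistent with a monotonically drifting reference potential that switches
abruptly. Under the default filter a step rings for ~1 ms at ~29% of its
amplitude; the default 30 µV amplitude keeps that residual below typical
detection thresholds so the prescribed ±1 ms exclusion window is
sufficient. Larger amplitudes are supported and stress the exclusion
logic rather than detection.

What the generator does *not* emulate: electrode drift, template
non-stationarity, overlapping-spike waveform superposition on shared
electrodes across units, correlated (non-white) noise, and realistic
artifact physics. Passing tests therefore demonstrate correctness of the
analysis rules and robust recovery under the stated statistical structure,
not performance on laboratory data.

Two regimes of the emulated study deserve explicit caveats. Binned-count
synchrony *rises* during simulated stimulation (many more common burst
events outweigh their smaller size), whereas the emulated experiments
report a decrease; reproducing that direction would require calibrating
unreported quantities, which is deliberately not done. And the
initiation-point map on the default dense-background session inherits the
onset-attribution limitation described above.

# Reproducibility and scale choices

Everything stochastic takes a seed: trace noise is seeded per electrode,
UMAP per unit, so lazily synthesized and materialised recordings are
bit-identical and re-running an analysis reproduces identical outputs
(`run_full_analysis()` writes MD5 checksums of all inputs and outputs to
its manifest). The test-suite sessions use 2/3/2-min, 20-unit traced
recordings for detection/sorting checks and full-scale (110-neuron,
20/30/20-min) spike-train sessions for burst and metric checks — sizes at
which every property is measurable while the whole suite stays
desk-runnable.

# Package shape

The orchestrator follows the classed-result idiom of R modelling packages:
`analyze_session()` returns an `mea_analysis` object with `print()`,
`summary()` and `plot()` methods, and each stage remains an exported
function operating on plain containers, so partial pipelines (e.g. burst
analysis on externally sorted trains) compose naturally. Internals are
base R plus compiled hot paths; file interchange uses HDF5 (`rhdf5`) for
traces and CSV/JSON for tables, configs and manifests.
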