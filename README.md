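# meaburst

Analysis of high-density microelectrode array (HD-MEA) recordings from
cultured neuronal networks under optical stimulation — built for sessions
in which sensory (DRG) neurons are stimulated and the downstream spinal
network is recorded before, during, and after stimulation.

The package turns raw multi-channel extracellular traces into:

* **spike trains** per electrode — zero-phase 100–3000 Hz Butterworth
  filtering; threshold at the trace mean minus 5 robust noise SDs, where
  SD is estimated as `median(|x − median(x)|)/0.6745`; negative-peak
  detection with a 2 ms keep-first refractory rule; exclusion of spikes
  within ±1 ms of stimulation pulses (artifact switching edges);
* **waveform clusters** (putative single neurons) per 9-electrode
  recording unit — 41-sample (2 ms) windows from all nine electrodes
  centred on the representative electrode's spikes, embedded in 2-D with
  UMAP (`n_neighbors = 20`, `min_dist = 0.2`) and clustered with DBSCAN
  (`min_samples = 5`, knee-selected radius); clusters of ≤ 50 spikes
  discarded;
* **network bursts** — any 100 ms window of the pooled raster holding
  > 50 spikes, merged across overlapping windows; each burst attributed
  to the cluster with the first spike after onset (its *initiation
  point*), mapped to electrode-unit locations per period;
* **activity statistics** — per-period firing rates; normalized rate
  change `(b − a)/(b + a)` (1 = newly active, 0 = unchanged); presence
  patterns across periods; burst-frequency fold changes; collective
  activity strength (mean per-burst participation %); binned pairwise
  Pearson synchrony; exact/approximate Wilcoxon signed-rank comparisons
  with Bonferroni correction;
* **marker colocalization** — fraction of nuclei within 10 µm of a
  marker point, with overlap de-duplication (several nuclei at one marker
  count once).

Because raw laboratory recordings are not redistributable, the package
ships a synthetic session generator (`simulate_session()`) producing
traces with full ground truth — per-electrode spike templates, baseline
and stimulus-locked firing, network bursts led by designated initiator
neurons, monotonic-drift stimulation artifacts — so the entire pipeline
is testable end to end.

## Worked example

```r
library(meaburst)

# a scaled synthetic session: 6 recording units, 2/3/2-minute periods
s <- simulate_session(n_units = 6, periods_min = c(2, 3, 2), seed = 42)
s
#> <mea_session>
#> <mea_recording> 54 electrodes (6 units), 420.0 s at 20 kHz [lazy traces]
#>   periods (s): 0 / 120 / 300 / 420; 36 stimulation pulses
#>   6 neurons, 24 ground-truth bursts, 2 initially inactive

a <- analyze_session(s$recording, burst = burst_params(min_spikes = 12),
                     seed = 42)
summary(a)
#> <mea_analysis> 6 waveform cluster(s) on 6 unit(s); 24 burst(s)
#>   presence: 66.7% in all periods, 33.3% absent before stimulation
#>   burst rate (/min) pre/in/post: 0.50 / 5.33 / 3.50 (fold in 10.7, post 7.0)
#>   collective activity strength (%) pre/in/post: 50.0 / 56.2 / 57.1
#>   mean pairwise r pre/in/post: 0.075 / 0.294 / 0.239 (in/pre 390%, post/pre 318%)
#>   3 initiator cluster(s) with >= 3 bursts
```

Reading the output: all six simulated neurons were recovered as exactly
one waveform cluster each; a third of them were silent before stimulation
(the two programmed inactive neurons of six); the network burst rate rose
~11-fold during stimulation and stayed ~7-fold elevated afterwards,
tracking the programmed regime. (The burst threshold is lowered to 12
spikes here because only six neurons are simulated; full-size sessions
use the default of 50.)

`plot(a)` draws the session raster with period boundaries and burst
onsets. `run_full_analysis(config)` executes the same chain from an HDF5
recording and stimulation CSV named in a JSON config, writing stage
tables, a metrics summary, and a manifest with MD5 checksums of every
input and output; identical configs reproduce byte-identical outputs.

Point-pattern colocalization is independent of the recording chain:

```r
g <- generate_colocalization_points(1000, 955, marker_fraction = 0.955,
                                    jitter_sd = 1, seed = 13)
marker_positive_fraction(g$nuclei, g$marker, radius = 10)
#> <colocalization> 952/1000 nuclei within 10 um of a marker (95.2%)
```

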