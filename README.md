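# engramr

Detection of **reverberations** and **engrams** of induced firing
patterns in neuronal network activity recordings.

Cultured neuronal networks that are briefly stimulated with a patterned
input — a single frequency (3–10 Hz) or a *doublet* pattern (two pulses
`d = 80–160 ms` apart, repeated every `P = 280–880 ms`) — can keep
expressing components of that pattern after the stimulus stops.
`engramr` is for experimenters and analysts who have per-cell activity
recordings (calcium fluorescence traces or spike-time tables) collected
under a test-pulse / prestim / stim / poststim paradigm and want to
quantify that persistence. It provides:

* a **synthetic-data generator** emulating the paradigm with known
  ground truth (which cells replay which component, cell types), so
  every stage is testable without any recording;
* **spike inference** from fluorescence by nonnegative deconvolution
  against an exponential kernel with MAD-based thresholding, and
  exclusion of slow-onset (glial) calcium waves by 10–90% rise time;
* **ISI statistics**: per-epoch inter-spike-interval histograms at one
  bin per frame (~20 ms); a cell "fires at" period `T` when it has ≥ 2
  ISIs with `|ISI − T| ≤ bin width` (the ±1-bin rule). The headline
  reverberation statistic is

  `pct_increase_total = 100 · (n_post − n_pre) / n_stim`

  on matched-ISI counts, with the companion recruitment measure
  `pct_cells_increase = 100 · (cells_post − cells_pre) / n_active`;
* an **engram classifier**: a two-layer bidirectional recurrent network
  (64 units per layer and direction, sequence → last, softmax readout,
  implemented from scratch with exact BPTT + Adam) trained on
  stimulation-epoch cycles vs ISI-shuffled nulls, then slid along each
  cell's sequence in 10–50 ms steps to produce per-cell confidence maps
  and merged engram events;
* **population statistics**: excitatory/inhibitory composition of the
  matched populations per epoch, and the overlap (Jaccard by default)
  between cells expressing the high- (`d`) vs low-frequency (`P`)
  components of a doublet pattern.

## Worked example

```r
library(engramr)

cfg     <- generator_config(n_cells = 200, reverb_fraction = 0.3, seed = 42)
pattern <- stim_pattern("single", frequency = 8)
rec     <- generate_raster(cfg, pattern)
rec$raster
#> <spike_raster> 200 cells, 33205 spikes, 170.0 s at 50 fps

views  <- segment(rec$raster, rec$timeline)
active <- select_active(rec$raster, rec$timeline)
m <- lapply(views[c("prestim", "stim", "poststim")], function(v)
  match_cells_at_period(compute_isis(v)[as.character(active$cells)],
                        period = 1/8, bin_width = 0.02))
reverberation_stats(m$prestim, m$stim, m$poststim,
                    n_active = length(active$cells), frequency = 8)
#> <reverberation_report> 8 Hz
#>   matched ISIs  pre/stim/post: 26.0 / 12594 / 6400.0
#>   matched cells pre/stim/post: 2 / 200 / 61 (of 200 active)
#>   pct_increase_total: 50.6%
#>   pct_cells_increase: 29.5%
```

Reading the output: before stimulation only 2 of 200 viable cells fired
at 8 Hz by chance; afterwards 61 did. The recruitment gain (61 − 2) /
200 = 29.5% recovers the generator's planted `reverb_fraction = 0.3`,
and `pct_increase_total` expresses the gain in 8 Hz ISIs relative to how
strongly the stimulus drove the network.

The full pipeline (generation → segmentation → ISI statistics →
optional classifier training and scanning → population statistics, with
CSV/JSON outputs and a checksummed manifest) runs from a JSON config:

```r
res <- run_pipeline(default_run_config(seed = 1), "out/")
```

or from the command line:

```sh
engram-echo all --config config.json --out out/ --seed 1 --figures
```

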