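---
title: "Detecting reverberations and engrams in neuronal network activity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting reverberations and engrams in neuronal network activity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(engramr)
```

## The problem

Cultured neuronal networks that are briefly driven with a patterned
stimulus can keep expressing components of that pattern after the
stimulus ends. `engramr` implements the full analysis chain needed to
quantify this at the level of per-cell activity recordings:

1. **`synthgen`** — a generator of synthetic recordings with the
   experimental paradigm structure and known ground truth;
2. **`spikes`** — spike inference from calcium fluorescence traces,
   with slow-onset (glial) event exclusion;
3. **`paradigm`** — epoch segmentation and viability (test-pulse)
   selection;
4. **`isistats`** — inter-spike-interval (ISI) histogram statistics and
   the reverberation percent-increase measures;
5. **`engramnet`** — a recurrent two-class sequence classifier trained
   on the stimulation epoch and scanned over the whole recording;
6. **`population`** — excitatory/inhibitory composition and
   high/low-frequency component overlap.

The recording paradigm has five ordered epochs: `test1` (sparse
0.2–0.5 Hz viability pulses), `prestim` (60 s spontaneous control),
`stim` (10 s patterned stimulation), `poststim` (60–90 s response
window), `test2` (viability re-check). Stimulation is either a single
frequency (3–10 Hz; 10 Hz is the resolvability ceiling at 20 ms
exposure) or a *doublet* pattern: two pulses `d` apart (80–160 ms),
repeated every `P` (280–880 ms).

## The statistics

**Reverberation (single frequencies).** Per epoch, per cell, ISIs are
successive spike-time differences. An ISI *matches* a target period `T`
iff `|ISI − T| ≤ bin_width`, with `bin_width` equal to the frame
exposure (~20 ms) — an alignment-free reading of "within ±1 histogram
bin". A cell matches if it has at least `min_matches = 2` matching ISIs
(one chance interval under Poisson background should not call a cell).
Two summary statistics are reported, because "percentage increase in
ISIs … normalized for the number of neurons firing" is ambiguous
between them:

* `pct_increase_total = 100 (n_post − n_pre) / n_stim` on matching-ISI
  counts (pre/post rate-normalized to a common 60 s when epoch
  durations differ);
* `pct_cells_increase = 100 (cells_post − cells_pre) / n_active` on
  matched-cell counts.

Under the generator, the second statistic recovers
`100 × reverb_fraction` directly (tested to ±5 points at zero jitter).

**Engrams (full patterns).** A two-class sequence classifier is trained
on the stimulation epoch: positives are one cell × one pattern cycle,
binarized at the exposure; negatives are ISI-shuffled versions of the
positives (alternatives: uniform noise, prestim slices). The trained
network then slides along each cell's sequence in 10–50 ms steps;
contiguous suprathreshold windows merge into *engram events*.

## Design choices and why

**Architecture.** The reference design is two stacked bidirectional
recurrent layers of 64 units (sequence → last) with a 2-way softmax
readout. We implement exactly that topology with plain tanh recurrence
instead of LSTM gates: sequences are ≤ 100 bins, so gating adds nothing
this task needs, and the network (with exact backpropagation through
time, Adam, and global-norm gradient clipping at 0.99) stays free of
heavyweight dependencies. Gradients are verified against finite
differences in the test suite. Training defaults are desk-scaled — the
epoch ceiling is 200, with early stopping at 100% training accuracy
(plus patience) and on loss plateaus; a run that hits the ceiling keeps
its best checkpoint and is flagged unconverged.

**ISI shuffle degeneracy.** Shuffling preserves the ISI multiset and
the first-spike offset. A clean doublet cycle, however, has exactly one
ISI: every permutation is the identity and the "null" would equal the
pattern. When no distinct permutation exists (fewer than two ISIs, or
all ISIs equal), the ISIs are re-drawn at random with spike count and
first-spike offset preserved, re-drawn until the binarized sequence
differs from its source. This keeps the two classes separable — the
condition under which training to 100% on the training patterns is
meaningful at all.

**Bin-centered binarization and aligned scanning.** Pattern-locked
spikes sit exactly on bin-edge times by construction, so floor-edge
binarization is knife-edged: one part in 10^16 of floating error, or
10 ms of biological jitter, flips the bin. Classifier windows therefore
collect spikes from `[start − bw/2, start + cycle − bw/2)` and round to
the nearest bin center, making the canonical pattern robust to sub-bin
jitter. For the same reason the sliding scan only scores windows whose
first spike falls in the first bin: every training sequence starts with
the pattern's first spike, so unaligned windows are out-of-distribution
for the classifier (and the sliding grid guarantees an aligned window
exists for every candidate event). Unscored windows get confidence 0,
as do windows with fewer than two spikes, which cannot contain a
pattern.

**Peak locations.** Regular trains put all their ISIs on a bin edge
(0.16 s is exactly eight 20 ms bins), so reporting a peak as its bin
*center* would sit half a bin off no matter how edges are aligned. Peak
locations are therefore reported as the mean of the ISIs inside the
peak bin — quantization-free, and exact for period-locked trains.

**Spike inference.** Fluorescence is deconvolved by first-order
inversion of the exponential kernel (`s_t = y_t − g y_{t−1}`,
`g = exp(−exposure/τ)`), after per-cell median centering; the noise
scale is a MAD taken before clipping at zero (clipping first would
halve it). One spike is emitted per suprathreshold local maximum of the
deconvolved signal, and a candidate must persist into the next frame
consistently with the kernel (`y_{t+1} − g² y_{t−1}` at least half the
detection margin) — a real transient always does, a single-frame noise
excursion rarely does. This keeps false positives below 0.1 spikes/min
at `threshold_sd = 4` on pure noise while preserving ≥95% recovery at
`threshold_sd ≈ 1.5` when frame noise reaches 0.2 × amplitude. The
threshold is deliberately a *required* argument: the right multiplier
is a property of the recording's noise, not of the algorithm.

**Glial wave exclusion.** Astrocytic events are recognized by slow
onset: the 10–90% rise time to the *first* local peak of a
suprathreshold run (measuring to the global maximum would misclassify
merged fast transients with a rising envelope), with the ascending limb
extended below the detection threshold so the measurement is not
truncated. Events rising slower than 1 s (default) are masked — ramp
and decay tail included — before deconvolution, and cells whose
suprathreshold area is more than half slow-wave are flagged
non-neuronal.

## What the generator emulates — and what it does not

Each cell fires homogeneous-Poisson background (default 0.2 Hz, a
mature low-bursting culture) throughout; responds to each test or
stimulation pulse with probability `stim_response_prob` (default 0.9);
and, if selected as a reverberating cell (a `reverb_fraction` of the
active cells, default 0.25), replays its assigned component — the full
pattern, or under `split_by_frequency` either the doublet interval or
the pattern period as a regular train — from poststim onset for
`reverb_duration` (default 20 s; the effect is transitory and its
duration is a free parameter, so this is a stated choice, not a fit).
Replayed spikes are jittered (`reverb_jitter_sd`, default 10 ms —
below one bin, consistent with replay ISIs concentrating within ±1
histogram bin) and fail at the same per-spike rate as driven ones;
without that failure mode a perfect whole-pattern replay would contain
no pattern-period ISI at all, whereas failures are exactly what creates
the third (pattern-period) histogram peak. A 5 ms refractory floor
removes degenerate ISIs. The calcium forward model adds an
instantaneous-rise exponential-decay transient per spike (τ = 0.5 s),
Gaussian frame noise, and optional slow-onset glial waves (linear ramp
with 2 s 10–90% rise, slow decay).

The generator is phenomenological: there is no synaptic circuit, no
bursting, no rate adaptation, no correlated population events, and
replay begins exactly at poststim onset. A green test therefore
establishes that the *analysis machinery* recovers what was put in —
rates, recruited fractions, component assignments, replay intervals —
not that any biological claim about real cultures is reproduced.
Headline effect sizes from real recordings (e.g. several-hundred-percent
increases) are covered only as direction-of-effect and
parameter-recovery properties.

## Numerical conventions

* Time is continuous seconds internally; quantization happens only at
  rendering and binning. Epochs are half-open `[start, end)`.
* Histogram bins start at 0 with width = exposure; modal ties break
  toward the lower bin; local maxima need no smoothing at this bin
  width, and peaks below 5% of the modal count are ignored by
  `isi_peaks()`.
* All randomness flows from explicit integer seeds (kept within 32-bit
  range); identical config + seed reproduces rasters, traces, trained
  weights and detection maps bit for bit.
* Interchange formats are plain text: rasters as `cell_id,spike_time_s`
  CSV, traces as wide CSV, configs/reports/manifests as JSON. (No HDF5:
  no R HDF5 binding is available in the supported environment.)

## Known limitations

* Single-frequency patterns give one spike per cycle, so the classifier
  null is weakly informative for them; the ISI statistics are the right
  tool there, the classifier is intended for doublet patterns.
* The E/I analysis consumes labels; it does not do image-based typing.
* The overlap statistic between high- and low-frequency populations has
  no canonical algebraic definition in the source material; Jaccard is
  the default, min- and mean-denominator variants are provided, and no
  acceptance value targets its magnitude.
* The two candidate denominators for the engram percent-increase
  (prestim count vs stimulation count) are both implemented; neither is
  presented as canonical.
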