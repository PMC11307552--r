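# Fixture builders shared across test files. Everything is generated in
# code; no data files.

# Regular spike train raster: one or more cells firing at `period` from
# `t0` for `duration` seconds.
regular_raster <- function(period, duration, n_cells = 1, t0 = 0,
                           total = duration, exposure = 0.02) {
  t <- t0 + seq(0, duration - 1e-9, by = period)
  spike_raster(rep(list(t), n_cells), duration = total,
               exposure = exposure)
}

# Minimal five-epoch timeline for hand-built rasters; test pulses every
# 2 s in the test epochs.
toy_timeline <- function(pattern, test1 = 10, prestim = 20, stim = 10,
                         poststim = 20, test2 = 10) {
  cfg <- generator_config(
    n_cells = 1,
    epoch_durations = c(test1 = test1, prestim = prestim, stim = stim,
                        poststim = poststim, test2 = test2))
  pattern$duration <- stim
  build_timeline(cfg, pattern)
}

# Doublet pulse train with optional per-spike dropout, pooled over cells.
doublet_train <- function(d, P, duration, onset = 0, dropout = 0,
                          n_cells = 1) {
  pat <- stim_pattern("doublet", doublet_isi = d, pattern_period = P,
                      onset = onset, duration = duration)
  t <- pattern_spike_times(pat)
  lapply(seq_len(n_cells), function(i) {
    if (dropout > 0) t[stats::runif(length(t)) >= dropout] else t
  })
}

# Quick generated recording used by several tests.
demo_recording <- function(seed = 1, n_cells = 60, frequency = 3, ...) {
  cfg <- generator_config(n_cells = n_cells, seed = seed, ...)
  generate_raster(cfg, stim_pattern("single", frequency = frequency))
}

# Clean doublet world for classifier tests: fully responsive, no
# background, so positives are exactly the pattern.
clean_doublet_world <- function(seed, n_cells = 30) {
  cfg <- generator_config(n_cells = n_cells, seed = seed,
                          background_rate = 0, reverb_fraction = 0,
                          stim_response_prob = 1, reverb_jitter_sd = 0)
  pat <- stim_pattern("doublet", doublet_isi = 0.16, pattern_period = 0.46)
  generate_raster(cfg, pat)
}
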