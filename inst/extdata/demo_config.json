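{
  "seed": 1,
  "generator": {
    "n_cells": 100,
    "background_rate": 0.2,
    "test_pulse_rate": 0.5,
    "epoch_durations": {
      "test1": 20,
      "prestim": 60,
      "stim": 10,
      "poststim": 60,
      "test2": 20
    },
    "reverb_fraction": 0.3,
    "reverb_duration": 20,
    "reverb_jitter_sd": 0.01,
    "component_assignment": "whole_pattern",
    "ei_fraction": 0.8,
    "inhibitory_reverb_odds": 1,
    "stim_response_prob": 0.9,
    "exposure": 0.02
  },
  "pattern": {
    "kind": "single",
    "frequency": 8,
    "doublet_isi": {},
    "pattern_period": {},
    "duration": 10
  },
  "spikes": {
    "use_traces": false,
    "decay_tau": 0.5,
    "threshold_sd": 4,
    "noise_sd": 0.1,
    "rise_time_threshold": 1
  },
  "paradigm": {
    "min_response_frac": 0.5,
    "response_window": 0.1
  },
  "isistats": {
    "min_matches": 2
  },
  "engramnet": {
    "enabled": false,
    "null_kind": "isi_shuffle",
    "hidden": 64,
    "max_epochs": 60,
    "batch_size": 100,
    "learning_rate": 0.005,
    "window_step": 0.02,
    "threshold": 0.5
  },
  "population": {
    "overlap_measure": "jaccard"
  }
}
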