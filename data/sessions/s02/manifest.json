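{
  "session_id": "s02",
  "group": "non_compulsive",
  "animal": "non_compulsive_rat01",
  "files": {
    "trials": "trials.csv",
    "tracking": "tracking.csv",
    "spikes": "spikes.csv",
    "units": "units.csv",
    "waveforms": "waveforms.csv",
    "truth": "ground_truth.csv"
  },
  "conventions": {
    "bin_width": 0.1,
    "time_origin": "session start",
    "time_unit": "s",
    "coordinate_unit": "px",
    "waveform_sample_rate": 30000
  },
  "sippers": {
    "left": [40, 120],
    "right": [600, 120]
  },
  "config": {
    "n_cs_plus": 48,
    "n_cs_minus": 48,
    "iti_set": [20, 28, 36, 44, 56, 68, 96, 120],
    "cs_duration": 4,
    "access_duration": 8,
    "cs_minus_exclusion": 3,
    "alternation_p": 0.6,
    "change_point_trial": 25,
    "p_approach_high": 0.9,
    "p_approach_low": 0.2,
    "p_correct_side": 0.9,
    "p_drink_given_correct": 0.95,
    "arena_width": 640,
    "arena_height": 240,
    "sipper_left": [40, 120],
    "sipper_right": [600, 120],
    "tracking_rate": 30,
    "tracking_noise_sd": 2,
    "session_lead_in": 30,
    "n_neurons": 60,
    "baseline_rate": 3,
    "signal_gains": {
      "non_compulsive": [0.5, 1, 1, 1]
    },
    "loading_spread": 0.1,
    "ei_fraction": 0.2,
    "rate_cap": 200,
    "seed": 2076509202
  },
  "config_hash": "0b68afd7"
}
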