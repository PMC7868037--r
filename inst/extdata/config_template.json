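{
  "params": {
    "baseline_plasma": 50,
    "baseline_mucus": 5,
    "handling_amp": 180,
    "handling_decay": 0.25,
    "pulse_amp": 750,
    "k_abs": 0.125,
    "k_elim": 0.05,
    "k_transfer": 0.0013,
    "k_mucus": 0.0045,
    "fish_sd_log": 0.3,
    "cv_plasma": 0.1095,
    "cv_mucus": 0.1266
  },
  "design": {
    "trials": [
      {
        "name": "ACTH",
        "treatment_tanks": 3,
        "control_tanks": 1
      },
      {
        "name": "cortisol",
        "treatment_tanks": 2,
        "control_tanks": 2
      }
    ],
    "fish_per_tank": 5,
    "sampling_times": [0, 2, 4, 8, 12, 24, 36, 48, 72, 84],
    "first_window": [0, 12],
    "second_window": [24, 84],
    "min_resample_gap": 24
  },
  "settings": {
    "chains": 3,
    "iterations": 100000,
    "thin": 3,
    "burnin_draws": 100,
    "seed": 1
  },
  "analysis": {
    "plasma_window": [0, 12],
    "mucus_window": [0, 84],
    "grid_step": 0.1,
    "pairing": "shuffle",
    "pairing_seed": 1,
    "align": "per_draw"
  },
  "seed": 1
}
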