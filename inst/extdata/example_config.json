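{
  "seed": 1,
  "n_participants": 2,
  "miss_rate": 0.0,
  "model": "WL",
  "params": {
    "alpha_win": 0.77,
    "alpha_loss": 0.52,
    "T_win": 0.35,
    "T_loss": 0.87
  },
  "models": ["RL", "WL", "HMM", "VOL"],
  "n_starts": 10,
  "n_schedules": 31,
  "n_reps": 10,
  "out_dir": "revlearn_out"
}
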