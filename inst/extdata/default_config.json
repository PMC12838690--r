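{
  "plant": {
    "threshold": 1,
    "gain": 60,
    "tau_c": 0.4,
    "sat_drive": 2,
    "speed_mean": 0.5,
    "speed_sd": 0.1,
    "speed_tau": 2,
    "turn_sigma": 6,
    "turn_tau": 1,
    "v_max": 10,
    "ang_max": 180,
    "amp_max": 3,
    "walk_noise": true,
    "variability": 0.45
  },
  "habituation": {
    "D_s": 0.02,
    "D_l": 0.0005,
    "I_s0": 0.08,
    "k_v": 1.5,
    "I_l": 0.002,
    "sigma_s": 0.005,
    "sigma_l": 0.001,
    "dt": 0.05,
    "speedup": 1
  },
  "controller": {
    "rule_bounds": [80, 150],
    "rule_target": 105,
    "eps_fire": 0.1,
    "util_discount": 0.99,
    "dev_threshold_deg": 10,
    "amp_range": [0, 3],
    "freq_range": [10, 200],
    "dur_range": [50, 500],
    "lambda": 0.995,
    "lr": 0.01,
    "momentum": 0.9,
    "n_premise": 50,
    "online_rls": true,
    "seed_batch": 3000
  },
  "scheduler": {
    "f_start": 25,
    "k_f": 5,
    "A1": 0.5,
    "IBI_min": 2,
    "IBI_max": 30,
    "k": 3
  },
  "baseline_pid": {
    "Kp": 0.8,
    "Ki": 0.05,
    "Kd": 0.2,
    "i_max": 2,
    "dev_threshold_deg": 10,
    "ibi_fixed": 2
  },
  "arena": {
    "width": 200,
    "height": 200,
    "target": [160, 160],
    "completion_radius": 8
  },
  "experiment": {
    "dt": 0.1,
    "duration": 360,
    "leg_budget": 60,
    "window_s": 30,
    "n_seeds": 20
  }
}
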