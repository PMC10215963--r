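{
  "session_dur_s": 60,
  "mu_rate_per_min": 8,
  "mu_dur_mean_s": 1.2,
  "mu_dur_sd_s": 0.4,
  "antagonist_rho": 0.5,
  "body_height_cm": 55,
  "limbs": ["left_leg", "right_leg"],
  "seed": 20230515
}
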