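{
  "n_cycles": 6,
  "phase_dur_mean_s": 1.5,
  "phase_dur_sd_s": 0.2,
  "baseline_uv": 5,
  "burst_amp_uv": 20,
  "response_prob_str": 0.7,
  "response_prob_shr": 0.7,
  "latency_pct_range": [10, 50],
  "burst_dur_mean_s": 0.4,
  "burst_dur_sd_s": 0.1,
  "noise_sd_uv": 0.8,
  "rate_hz": 1926,
  "joint": "knee",
  "side": "L",
  "seed": 20230515
}
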