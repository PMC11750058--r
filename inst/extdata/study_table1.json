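{
  "dgp": {
    "n_sites": 10,
    "n_years": 10,
    "oce_sd": 1,
    "recruit_slope": -2,
    "recruit_mean": 10,
    "temp_slope": 2,
    "temp_mean": 15,
    "temp_within_sd": 1,
    "effect_temp": 1,
    "effect_recruit": 1,
    "noise_sd": 1,
    "seed": 1,
    "variant": "snail"
  },
  "n_reps": 100,
  "interval_rule": {"kind": "two_se", "level": 0.95}
}
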