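{
  "n_exp1": 24,
  "n_exp2": 31,
  "w": "uniform",
  "sigma_prior": 5.7,
  "sd_nociceptor": 20,
  "sigma_rating": 3,
  "s_low": 20,
  "s_high": 80
}
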