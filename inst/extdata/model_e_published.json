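{
  "family": "E",
  "transform": "none",
  "shift_offset": 0,
  "n_train": 89,
  "residual_sd": 4.35,
  "r_squared": 0.990,
  "eps": 1e-4,
  "training_range": {
    "delta_ct": [-8.16, 34.45]
  },
  "params": {
    "YM": 99.53,
    "Y0": 0.02733,
    "k": 0.7218
  },
  "source": "published"
}
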