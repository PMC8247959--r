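{
  "description": "synthetic noise-free catalyst-free pH-rate profile generated from the reference background parameters",
  "truth": {
    "kH": 0.0024,
    "kH2O": 1.3e-07,
    "kOH": 0.1,
    "kcat": 0,
    "Ka": null,
    "KW": 6.2e-13
  },
  "cat_conc": 0
}
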