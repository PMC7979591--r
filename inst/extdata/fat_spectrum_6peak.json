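{
  "comment": "Six-peak liver triglyceride spectrum, shifts in ppm relative to water, amplitudes normalized to sum to 1. Standard literature values; the scanner vendor's in-product peak table is unpublished, so results computed with this spectrum are labeled as using the package default.",
  "shift_ppm": [-3.80, -3.40, -2.60, -1.94, -0.39, 0.60],
  "amplitude": [0.087, 0.694, 0.128, 0.004, 0.039, 0.048]
}
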