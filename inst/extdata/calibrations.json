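[
  {"label": "henninger", "slope": 0.436, "intercept": 4.964},
  {"label": "wood", "slope": 0.455, "intercept": -3.617},
  {"label": "garbowski", "slope": 0.573, "intercept": -2.507},
  {"label": "hankins", "slope": 0.502, "intercept": -8.145},
  {"label": "qdixon_cross", "slope": 0.434, "intercept": 6.135},
  {"label": "qdixon_wip_cross", "slope": 0.429, "intercept": 5.682}
]
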