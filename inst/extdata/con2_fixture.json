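{
  "family": "CON2",
  "fragment_length": 538,
  "n_columns": 8,
  "groups": {
    "1": ["Da_KEW-0522816", "Da_KEW-0661919", "Da_KEW-0521613", "Dp_KEW-0661849"],
    "2": ["Ds_78", "Dc_PI-562652", "Dc_PI-577069", "Dc_PI-371724", "De_PI-665545", "Df_PI-577075"],
    "3": ["Hp_KEW-065160", "Km_KEW-0096838"],
    "4": ["Dd_W6-39054"]
  },
  "reference_vs_group": {
    "1": {"differences": 1, "matches": 7},
    "2": {"differences": 7, "matches": 1},
    "3": {"differences": 5, "matches": 3},
    "4": {"differences": 6, "matches": 2}
  },
  "notes": [
    "Zygosity structure of the CON2 worked example; 13 samples across four profile groups.",
    "T. phleoides is absent from the CON2 grouping although 14 accessions were studied; the fixture uses exactly the 13 grouped samples.",
    "Base identities and column positions are synthetic conventions; only zygosity states and match/difference counts are reconstructable."
  ]
}
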