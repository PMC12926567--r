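{
  "name": "HBB_GFP_amplicon",
  "length": 6000,
  "cds_intervals": [
    [600, 692],
    [822, 1045],
    [1895, 2024]
  ],
  "cut_site": 621,
  "sickle_position": 619,
  "donor_base": "A",
  "marker_interval": [2283, 2286],
  "marker_alleles": {
    "GFP": "TAC",
    "BFP": "CAT"
  }
}
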