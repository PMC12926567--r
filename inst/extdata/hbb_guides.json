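[
  {
    "name": "R-66S",
    "protospacer": "GTAACGGCAGACTTCTCCAC",
    "pam": "AGG",
    "strand": "-"
  },
  {
    "name": "R-02",
    "protospacer": "GTCTGCCGTTACTGCCCTGT",
    "pam": "GGG",
    "strand": "+"
  }
]
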