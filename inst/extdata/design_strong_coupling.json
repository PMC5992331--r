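[
  {
    "quantity": "yield:R3/R1",
    "op": "<",
    "value": 0.5,
    "region": "target"
  },
  {
    "quantity": "rate:R4",
    "op": ">",
    "value": 0,
    "region": "desired"
  }
]
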