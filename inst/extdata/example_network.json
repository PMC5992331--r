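{
  "metabolites": [
    "S",
    "A",
    "B",
    "C",
    "P",
    "Q"
  ],
  "reactions": [
    {
      "id": "R1",
      "reversible": false,
      "lb": 0,
      "ub": "inf",
      "stoichiometry": {
        "S": 1
      }
    },
    {
      "id": "R2",
      "reversible": false,
      "lb": 0,
      "ub": "inf",
      "stoichiometry": {
        "Q": -1
      }
    },
    {
      "id": "R3",
      "reversible": false,
      "lb": 0,
      "ub": "inf",
      "stoichiometry": {
        "P": -1
      }
    },
    {
      "id": "R4",
      "reversible": false,
      "lb": 0,
      "ub": "inf",
      "stoichiometry": {
        "B": -1
      }
    },
    {
      "id": "R5",
      "reversible": false,
      "lb": 0,
      "ub": "inf",
      "stoichiometry": {
        "S": -1,
        "A": 1
      }
    },
    {
      "id": "R6",
      "reversible": false,
      "lb": 0,
      "ub": "inf",
      "stoichiometry": {
        "S": -2,
        "C": 1,
        "P": 1
      }
    },
    {
      "id": "R7",
      "reversible": false,
      "lb": 0,
      "ub": "inf",
      "stoichiometry": {
        "A": -1,
        "C": 1
      }
    },
    {
      "id": "R8",
      "reversible": false,
      "lb": 0,
      "ub": "inf",
      "stoichiometry": {
        "S": -1,
        "Q": 1
      }
    },
    {
      "id": "R9",
      "reversible": false,
      "lb": 0,
      "ub": "inf",
      "stoichiometry": {
        "S": -1,
        "P": 1
      }
    },
    {
      "id": "R10",
      "reversible": false,
      "lb": 0,
      "ub": "inf",
      "stoichiometry": {
        "B": 1,
        "C": -1
      }
    },
    {
      "id": "R11",
      "reversible": true,
      "lb": "-inf",
      "ub": "inf",
      "stoichiometry": {
        "A": -1,
        "B": 1
      }
    }
  ],
  "constraints": []
}
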