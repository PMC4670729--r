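{
  "metabolites": [
    {
      "id": "GLC"
    },
    {
      "id": "TRI"
    },
    {
      "id": "GLY"
    },
    {
      "id": "ATP"
    },
    {
      "id": "ADP"
    },
    {
      "id": "O2"
    },
    {
      "id": "BIO"
    }
  ],
  "reactions": [
    {
      "id": "EX_glc",
      "metabolites": {
        "GLC": -1
      },
      "lower_bound": -10,
      "upper_bound": 0
    },
    {
      "id": "GLK",
      "metabolites": {
        "GLC": -1,
        "TRI": 2
      },
      "lower_bound": 0,
      "upper_bound": 1000
    },
    {
      "id": "G2G",
      "metabolites": {
        "TRI": -1,
        "GLY": 1
      },
      "lower_bound": 0,
      "upper_bound": 1000
    },
    {
      "id": "OXI",
      "metabolites": {
        "TRI": -1,
        "ATP": 13.5,
        "ADP": -13.5,
        "O2": -3
      },
      "lower_bound": 0,
      "upper_bound": 1000
    },
    {
      "id": "BIOS",
      "metabolites": {
        "TRI": -1.5,
        "ATP": -10,
        "ADP": 10,
        "BIO": 1
      },
      "lower_bound": 0,
      "upper_bound": 1000
    },
    {
      "id": "EX_bio",
      "metabolites": {
        "BIO": -1
      },
      "lower_bound": 0,
      "upper_bound": 1000
    },
    {
      "id": "NGAM",
      "metabolites": {
        "ATP": -1,
        "ADP": 1
      },
      "lower_bound": 0,
      "upper_bound": 1000
    },
    {
      "id": "EX_o2",
      "metabolites": {
        "O2": -1
      },
      "lower_bound": -1000,
      "upper_bound": 1000
    },
    {
      "id": "EX_gly",
      "metabolites": {
        "GLY": -1
      },
      "lower_bound": 0,
      "upper_bound": 1000
    }
  ],
  "annotation": {
    "exchanges": {
      "glucose": "EX_glc",
      "product": "EX_gly",
      "oxygen": "EX_o2"
    },
    "maintenance": "NGAM"
  }
}
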