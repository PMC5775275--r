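{
  "places": [
    {
      "name": "AMP",
      "initial": 0,
      "clamped": false
    },
    {
      "name": "Asn",
      "initial": 0,
      "clamped": false
    },
    {
      "name": "ASNe",
      "initial": 0,
      "clamped": false
    },
    {
      "name": "ASNe_Gln",
      "initial": 0,
      "clamped": false
    },
    {
      "name": "ASNe_NH3",
      "initial": 0,
      "clamped": false
    },
    {
      "name": "Asp",
      "initial": 0,
      "clamped": false
    },
    {
      "name": "ATP",
      "initial": 0,
      "clamped": true
    },
    {
      "name": "bAsp_AMP_ASNe_NH3",
      "initial": 0,
      "clamped": false
    },
    {
      "name": "Gln",
      "initial": 0,
      "clamped": false
    },
    {
      "name": "Glu",
      "initial": 0,
      "clamped": false
    },
    {
      "name": "Mg",
      "initial": 0,
      "clamped": true
    }
  ],
  "reactions": [
    {
      "name": "r1",
      "substrates": {
        "ASNe": 1,
        "Gln": 1
      },
      "products": {
        "ASNe_Gln": 1
      },
      "rate_constant": "k1"
    },
    {
      "name": "r2",
      "substrates": {
        "ASNe_Gln": 1
      },
      "products": {
        "Glu": 1,
        "ASNe_NH3": 1
      },
      "rate_constant": "k2"
    },
    {
      "name": "r3",
      "substrates": {
        "ASNe_NH3": 1,
        "Asp": 1,
        "ATP": 1,
        "Mg": 1
      },
      "products": {
        "bAsp_AMP_ASNe_NH3": 1,
        "Mg": 1
      },
      "rate_constant": "k3"
    },
    {
      "name": "r4",
      "substrates": {
        "bAsp_AMP_ASNe_NH3": 1
      },
      "products": {
        "Asn": 1,
        "ASNe": 1,
        "AMP": 1
      },
      "rate_constant": "k4"
    },
    {
      "name": "D",
      "substrates": {
        "ASNe_NH3": 1
      },
      "products": {
        "ASNe": 1
      },
      "rate_constant": "kD"
    }
  ]
}
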