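{
  "format": "feedcircuit-network",
  "version": 1,
  "units": [
    {
      "id": "AgRP",
      "rule": true
    },
    {
      "id": "POMC",
      "rule": true
    },
    {
      "id": "NGABA",
      "rule": true
    },
    {
      "id": "OXT",
      "rule": true
    },
    {
      "id": "MCH",
      "rule": true
    },
    {
      "id": "OX",
      "rule": true
    },
    {
      "id": "LHGal",
      "rule": true
    },
    {
      "id": "NT",
      "rule": true
    },
    {
      "id": "NTSCA",
      "rule": false
    },
    {
      "id": "NTSGLP1",
      "rule": false
    },
    {
      "id": "VTA",
      "rule": false
    },
    {
      "id": "NAc",
      "rule": false
    },
    {
      "id": "FI",
      "rule": false
    }
  ],
  "receptors": [
    {
      "unit": "AgRP",
      "receptor": "LepRB",
      "sign": -1,
      "hook": "none",
      "sources": "substance:leptin"
    },
    {
      "unit": "AgRP",
      "receptor": "GHSR",
      "sign": 1,
      "hook": "none",
      "sources": "substance:ghrelin"
    },
    {
      "unit": "AgRP",
      "receptor": "FHT1BR",
      "sign": -1,
      "hook": "none",
      "sources": "substance:FHT drug:FHT1Bag"
    },
    {
      "unit": "POMC",
      "receptor": "LepRB",
      "sign": 1,
      "hook": "none",
      "sources": "substance:leptin"
    },
    {
      "unit": "POMC",
      "receptor": "Y1R",
      "sign": -1,
      "hook": "none",
      "sources": "unit:AgRP:NPY"
    },
    {
      "unit": "POMC",
      "receptor": "GABAR",
      "sign": -1,
      "hook": "none",
      "sources": "unit:AgRP:GABA unit:NGABA:GABA"
    },
    {
      "unit": "POMC",
      "receptor": "FHT2CR",
      "sign": 1,
      "hook": "risperidone_halving",
      "sources": "substance:FHT drug:FHT2Cag"
    },
    {
      "unit": "NGABA",
      "receptor": "LepRB",
      "sign": -1,
      "hook": "none",
      "sources": "substance:leptin"
    },
    {
      "unit": "OXT",
      "receptor": "MCR",
      "sign": 1,
      "hook": "melanocortin_inverse_agonism",
      "sources": "unit:POMC:aMSH drug:aMSHx -unit:AgRP:AgRP"
    },
    {
      "unit": "OXT",
      "receptor": "GABAR",
      "sign": -1,
      "hook": "none",
      "sources": "unit:AgRP:GABA"
    },
    {
      "unit": "OXT",
      "receptor": "Y1R",
      "sign": -1,
      "hook": "none",
      "sources": "unit:AgRP:NPY"
    },
    {
      "unit": "OXT",
      "receptor": "MCHR",
      "sign": -1,
      "hook": "none",
      "sources": "unit:MCH:MCH"
    },
    {
      "unit": "MCH",
      "receptor": "GLUR",
      "sign": 1,
      "hook": "none",
      "sources": "substance:glucose"
    },
    {
      "unit": "OX",
      "receptor": "GLUR",
      "sign": -1,
      "hook": "none",
      "sources": "substance:glucose"
    },
    {
      "unit": "OX",
      "receptor": "GHSR",
      "sign": 1,
      "hook": "none",
      "sources": "substance:ghrelin"
    },
    {
      "unit": "OX",
      "receptor": "GalR",
      "sign": -1,
      "hook": "none",
      "sources": "unit:LHGal:Gal"
    },
    {
      "unit": "OX",
      "receptor": "AgRPR",
      "sign": 1,
      "hook": "none",
      "sources": "unit:AgRP:AgRP"
    },
    {
      "unit": "OX",
      "receptor": "POMCR",
      "sign": -1,
      "hook": "none",
      "sources": "unit:POMC:aMSH drug:aMSHx"
    },
    {
      "unit": "LHGal",
      "receptor": "LepRB",
      "sign": 1,
      "hook": "none",
      "sources": "substance:leptin"
    },
    {
      "unit": "NT",
      "receptor": "LepRB",
      "sign": 1,
      "hook": "none",
      "sources": "substance:leptin"
    },
    {
      "unit": "NTSCA",
      "receptor": "LepRB",
      "sign": 1,
      "hook": "none",
      "sources": "substance:leptin"
    },
    {
      "unit": "NTSCA",
      "receptor": "GHSR",
      "sign": -1,
      "hook": "none",
      "sources": "substance:ghrelin"
    },
    {
      "unit": "NTSCA",
      "receptor": "OXR",
      "sign": -1,
      "hook": "none",
      "sources": "unit:OX:OX"
    },
    {
      "unit": "NTSCA",
      "receptor": "OXTR",
      "sign": 1,
      "hook": "none",
      "sources": "unit:OXT:OXT"
    },
    {
      "unit": "NTSCA",
      "receptor": "CCKR",
      "sign": 1,
      "hook": "ntsca_cck_gate",
      "sources": "substance:CCK"
    },
    {
      "unit": "NTSGLP1",
      "receptor": "LepRB",
      "sign": 1,
      "hook": "none",
      "sources": "substance:leptin"
    },
    {
      "unit": "NTSGLP1",
      "receptor": "AR",
      "sign": 1,
      "hook": "none",
      "sources": "unit:NTSCA:CA"
    },
    {
      "unit": "VTA",
      "receptor": "LepRB",
      "sign": -1,
      "hook": "none",
      "sources": "substance:leptin"
    },
    {
      "unit": "VTA",
      "receptor": "GHSR",
      "sign": 1,
      "hook": "none",
      "sources": "substance:ghrelin"
    },
    {
      "unit": "VTA",
      "receptor": "OXR",
      "sign": 1,
      "hook": "none",
      "sources": "unit:OX:OX"
    },
    {
      "unit": "VTA",
      "receptor": "NTR",
      "sign": 1,
      "hook": "none",
      "sources": "unit:NT:NT"
    },
    {
      "unit": "VTA",
      "receptor": "GLP1R",
      "sign": -1,
      "hook": "none",
      "sources": "unit:NTSGLP1:GLP1 drug:GLP1x"
    },
    {
      "unit": "NAc",
      "receptor": "DR",
      "sign": -1,
      "hook": "none",
      "sources": "unit:VTA:DA"
    },
    {
      "unit": "NAc",
      "receptor": "Y1R",
      "sign": -1,
      "hook": "none",
      "sources": "unit:AgRP:NPY"
    },
    {
      "unit": "NAc",
      "receptor": "MCHR",
      "sign": -1,
      "hook": "none",
      "sources": "unit:MCH:MCH"
    },
    {
      "unit": "NAc",
      "receptor": "GLP1R",
      "sign": 1,
      "hook": "none",
      "sources": "unit:NTSGLP1:GLP1 drug:GLP1x"
    },
    {
      "unit": "FI",
      "receptor": "NAcR",
      "sign": -1,
      "hook": "none",
      "sources": "unit:NAc:NAc"
    },
    {
      "unit": "FI",
      "receptor": "NTSCAR",
      "sign": -1,
      "hook": "none",
      "sources": "unit:NTSCA:CA"
    }
  ],
  "releases": {
    "AgRP": ["AgRP", "NPY", "GABA"],
    "POMC": "aMSH",
    "NGABA": "GABA",
    "OXT": "OXT",
    "MCH": "MCH",
    "OX": "OX",
    "LHGal": "Gal",
    "NT": "NT",
    "NTSCA": "CA",
    "NTSGLP1": "GLP1",
    "VTA": "DA",
    "NAc": "NAc"
  },
  "output_stage_order": ["NTSCA", "NTSGLP1", "VTA", "NAc", "FI"],
  "substances": ["leptin", "ghrelin", "CCK", "FHT", "glucose"],
  "drugs": ["risperidone", "FHT2Cag", "FHT1Bag", "aMSHx", "GLP1x"],
  "fi": "FI",
  "n_params": 51
}
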