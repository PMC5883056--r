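[
  {"numeric": 3,  "symbol": "C=O",  "hydrogen": false, "rule": "carbonyl_carbon",        "description": "carbonyl / carboxyl carbon"},
  {"numeric": 2,  "symbol": "C=C",  "hydrogen": false, "rule": "vinylic_carbon",         "description": "vinylic (sp2, non-aromatic) carbon"},
  {"numeric": 37, "symbol": "CB",   "hydrogen": false, "rule": "aromatic_carbon",        "description": "aromatic carbon"},
  {"numeric": 1,  "symbol": "CR",   "hydrogen": false, "rule": "alkyl_carbon",           "description": "alkyl (sp3) carbon"},
  {"numeric": 7,  "symbol": "O=C",  "hydrogen": false, "rule": "carbonyl_oxygen",        "description": "carbonyl oxygen"},
  {"numeric": 59, "symbol": "OFUR", "hydrogen": false, "rule": "aromatic_oxygen",        "description": "aromatic (furan-type) oxygen"},
  {"numeric": 6,  "symbol": "OR",   "hydrogen": false, "rule": "ether_hydroxyl_oxygen",  "description": "alcohol / ether oxygen"},
  {"numeric": 38, "symbol": "NPYD", "hydrogen": false, "rule": "pyridine_nitrogen",      "description": "pyridine-type aromatic nitrogen"},
  {"numeric": 39, "symbol": "NPYL", "hydrogen": false, "rule": "pyrrole_nitrogen",       "description": "pyrrole-type aromatic nitrogen"},
  {"numeric": 10, "symbol": "NC=O", "hydrogen": false, "rule": "amide_nitrogen",         "description": "amide nitrogen"},
  {"numeric": 8,  "symbol": "NR",   "hydrogen": false, "rule": "amine_nitrogen",         "description": "amine (sp3) nitrogen"},
  {"numeric": 15, "symbol": "S",    "hydrogen": false, "rule": "thio_sulfur",            "description": "thiol / thioether sulfur"},
  {"numeric": 11, "symbol": "F",    "hydrogen": false, "rule": "fluorine",               "description": "fluorine"},
  {"numeric": 12, "symbol": "CL",   "hydrogen": false, "rule": "chlorine",               "description": "chlorine"},
  {"numeric": 13, "symbol": "BR",   "hydrogen": false, "rule": "bromine",                "description": "bromine"},
  {"numeric": 14, "symbol": "I",    "hydrogen": false, "rule": "iodine",                 "description": "iodine"},
  {"numeric": 24, "symbol": "HOCO", "hydrogen": true,  "rule": "h_on_carboxyl_oxygen",   "description": "hydroxyl hydrogen of a carboxylic acid"},
  {"numeric": 29, "symbol": "HOCC", "hydrogen": true,  "rule": "h_on_enol_phenol_oxygen","description": "phenolic / enolic hydroxyl hydrogen"},
  {"numeric": 21, "symbol": "HOR",  "hydrogen": true,  "rule": "h_on_oxygen",            "description": "alcohol hydroxyl hydrogen"},
  {"numeric": 23, "symbol": "HNR",  "hydrogen": true,  "rule": "h_on_nitrogen",          "description": "hydrogen on nitrogen"},
  {"numeric": 5,  "symbol": "HC",   "hydrogen": true,  "rule": "h_on_carbon",            "description": "hydrogen on carbon"}
]
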