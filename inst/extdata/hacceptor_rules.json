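{
  "elements": ["N", "O"],
  "exclude": ["positive_charge", "amide_nitrogen", "pyrrole_type_nitrogen"],
  "description": "N and O atoms count as hydrogen-bond acceptors unless an exclusion rule fires: positively charged N/O; amide or imide nitrogen (single-bonded to a carbonyl carbon); pyrrole-type aromatic nitrogen (aromatic N carrying an H or three sigma bonds)."
}
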