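- step: add_amine
  property: volume
  lower: 0.1
  upper: 1
  unit: mL
  scale: linear
- step: prestir
  property: time
  lower: 0
  upper: 30
  unit: min
  scale: linear
- step: add_acid
  property: volume
  lower: 0.5
  upper: 3
  unit: mL
  scale: linear
- step: add_isocyanide
  property: volume
  lower: 0.1
  upper: 1
  unit: mL
  scale: linear
- step: stir_rxn
  property: time
  lower: 2
  upper: 18
  unit: h
  scale: linear
- step: heat_rxn
  property: temp
  lower: 25
  upper: 60
  unit: degC
  scale: linear
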