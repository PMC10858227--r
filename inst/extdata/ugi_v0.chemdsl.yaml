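id: ugi
version: 0
metadata:
  title: Four-component condensation
steps:
  - id: add_ald
    name: Add
    properties:
      reagent: benzaldehyde
      volume: 0.2 mL
  - id: add_amine
    name: Add
    properties:
      reagent: benzylamine
      volume: 0.5 mL
  - id: prestir
    name: Stir
    properties:
      time: 5 min
  - id: add_acid
    name: Add
    properties:
      reagent: fluorobenzoic_acid
      volume: 1 mL
  - id: add_isocyanide
    name: Add
    properties:
      reagent: isocyanide
      volume: 0.42 mL
  - id: heat_rxn
    name: HeatChill
    properties:
      temp: 25 degC
  - id: stir_rxn
    name: Stir
    properties:
      time: 4 h
  - id: add_std
    name: Add
    properties:
      reagent: difluorobenzene
      volume: 5 mL
  - id: analyze
    name: Analyze
    properties:
      instrument: nmr
      sample_volume: 2.5 mL
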