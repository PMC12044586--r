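# Run configuration: derivatizing matrices, adducts, and functional-group
# pattern sets.  New matrices/adducts/patterns can be added here without
# code changes; CLI flags override these defaults.
defaults:
  ppm: 2.0
  bin_size: 0.01
  polarity: positive
patterns:
  phenolic_hydroxyl:
    query: "[OX2H][c]"
  primary_amine:
    query: "[NX3;H2][#6]"
    exclusions:
      - "[NX3;H2][CX3]=[OX1]"
      - "[NX3;H2][SX4](=[OX1])=[OX1]"
  secondary_amine:
    query: "[NX3;H1]([#6])[#6]"
    exclusions:
      - "[NX3;H1]([#6])[CX3]=[OX1]"
      - "[NX3;H1]([#6])[SX4](=[OX1])=[OX1]"
  carboxylic_acid:
    query: "[CX3](=[OX1])[OX2H]"
matrices:
  FMP-10:
    reagent: C20H15FN        # intact reagent cation, +1
    leaving_group: HF        # neutral lost per tagging reaction
    target_patterns: [phenolic_hydroxyl, primary_amine, secondary_amine]
    losses: {A: CH3, B: H}   # charge-reduction loss cations
    max_tags: 3
    diagnostic_adducts: {phenolic_hydroxyl: H2O, primary_amine: NH3}
  AMPP:
    reagent: C12H13N2
    leaving_group: H2O
    target_patterns: [carboxylic_acid]
    losses: {A: CH3, B: H}
    max_tags: 1
adducts:
  "[M+H]+":     {add: H,  remove: "",   charge: 1}
  "[M+Na]+":    {add: Na, remove: "",   charge: 1}
  "[M+K]+":     {add: K,  remove: "",   charge: 1}
  "[M-H]-":     {add: "", remove: H,    charge: -1}
  "[M+Cl]-":    {add: Cl, remove: "",   charge: -1}
  "[M+Na-2H]-": {add: Na, remove: H2,   charge: -1}
  "[M+K-2H]-":  {add: K,  remove: H2,   charge: -1}
  "[M-H2O-H]-": {add: "", remove: H3O,  charge: -1}
exclude_peaks: []            # matrix/reagent peaks to skip during annotation
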