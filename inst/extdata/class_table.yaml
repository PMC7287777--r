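# Lipid class table and fragment rule set (versioned data file).
# Core formulas are the neutral glycerophospho-backbones before acyl
# condensation; masses are always recomputed from formulas, never stored.
version: 1
classes:
  PA:     {kind: glycerophospholipid, core: C3H9O6P,    n_acyl: 2, choline: false, elution_rank: 2.5}
  PC:     {kind: glycerophospholipid, core: C8H20NO6P,  n_acyl: 2, choline: true,  elution_rank: 6, default_rt: 15.3}
  PE:     {kind: glycerophospholipid, core: C5H14NO6P,  n_acyl: 2, choline: false, elution_rank: 3, default_rt: 10.2}
  PG:     {kind: glycerophospholipid, core: C6H15O8P,   n_acyl: 2, choline: false, elution_rank: 1, default_rt: 7.2}
  PI:     {kind: glycerophospholipid, core: C9H19O11P,  n_acyl: 2, choline: false, elution_rank: 2, default_rt: 8.5}
  PS:     {kind: glycerophospholipid, core: C6H14NO8P,  n_acyl: 2, choline: false, elution_rank: 4.5}
  LPC:    {kind: glycerophospholipid, core: C8H20NO6P,  n_acyl: 1, choline: true,  elution_rank: 8, default_rt: 17.3}
  LPE:    {kind: glycerophospholipid, core: C5H14NO6P,  n_acyl: 1, choline: false, elution_rank: 5, default_rt: 14.0}
  SM:     {kind: sphingolipid, hexoses: 0, choline: true,  elution_rank: 7, default_rt: 16.2}
  Cer:    {kind: sphingolipid, hexoses: 0, choline: false, elution_rank: 0.5}
  HexCer: {kind: sphingolipid, hexoses: 1, choline: false, elution_rank: 0.6}
  Hex2Cer: {kind: sphingolipid, hexoses: 2, choline: false, elution_rank: 0.7}
  Hex3Cer: {kind: sphingolipid, hexoses: 3, choline: false, elution_rank: 0.8}
# Adduct/ion deltas are built in code from first principles (proton,
# electron, Na, CH3, HCOO, CH3COO); this block only declares per-class
# applicability beyond the default rules.
ions:
  choline_only: ["[M-CH3]-"]
# Class-diagnostic fragment ions. m/z is computed from the charged formula
# at load time; 'note' describes the chemistry of the ion.
diagnostics:
  - label: phosphocholine head
    formula: C5H15NO4P
    charge: 1
    polarity: positive
    classes: [PC, LPC, SM]
    note: protonated phosphocholine from choline-bearing lipids
  - label: demethylated glycerophosphocholine head
    formula: C7H15NO5P
    charge: -1
    polarity: negative
    classes: [PC, LPC]
    note: cyclic glycerophosphocholine head fragment of [M-CH3]- precursors
  - label: glycerophosphoethanolamine head
    formula: C5H11NO5P
    charge: -1
    polarity: negative
    classes: [PE, LPE]
    note: dehydrated glycerophosphoethanolamine anion
  - label: inositol phosphate head
    formula: C6H10O8P
    charge: -1
    polarity: negative
    classes: [PI]
    note: inositol monophosphate anion minus water
  - label: sphingoid d18:1 base
    formula: C18H34N
    charge: 1
    polarity: positive
    classes: [SM, Cer, HexCer, Hex2Cer, Hex3Cer]
    note: sphingosine backbone cation after loss of two waters
  - label: sphingoid d16:1 base
    formula: C16H30N
    charge: 1
    polarity: positive
    classes: [SM, Cer, HexCer, Hex2Cer, Hex3Cer]
    note: C16 sphingosine backbone cation after loss of two waters
  - label: sphingoid d18:2 base
    formula: C18H32N
    charge: 1
    polarity: positive
    classes: [SM, Cer, HexCer, Hex2Cer, Hex3Cer]
    note: sphingadiene backbone cation after loss of two waters
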