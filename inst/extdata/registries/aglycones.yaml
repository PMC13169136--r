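# Aglycones recognised from the residual fragment after a sugar neutral loss,
# looked up by the m/z of their deprotonated anion ([M-H]- of `formula`).
# Isobaric pairs (luteolin/kaempferol, nepetin/isorhamnetin) are reported as
# either/or unless a retention-time prior resolves them.
aglycones:
  - { name: myricetin,     formula: C15H10O8, type: flavonoid }
  - { name: quercetin,     formula: C15H10O7, type: flavonoid }
  - { name: luteolin,      formula: C15H10O6, type: flavonoid }
  - { name: kaempferol,    formula: C15H10O6, type: flavonoid }
  - { name: patuletin,     formula: C16H12O8, type: flavonoid }
  - { name: nepetin,       formula: C16H12O7, type: flavonoid }
  - { name: isorhamnetin,  formula: C16H12O7, type: flavonoid }
  - { name: apigenin,      formula: C15H10O5, type: flavonoid }
  - { name: genkwanin,     formula: C16H12O5, type: flavonoid }
  - { name: hydroxybenzoic acid,  formula: C7H6O3,  type: phenolic acid }
  - { name: protocatechuic acid,  formula: C7H6O4,  type: phenolic acid }
  - { name: vanillic acid,        formula: C8H8O4,  type: phenolic acid }
  - { name: syringic acid,        formula: C9H10O5, type: phenolic acid }
  - { name: caffeic acid,         formula: C9H8O4,  type: phenolic acid }
  - { name: coumaric acid,        formula: C9H8O3,  type: phenolic acid }
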