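# Sugar (and sugar-conjugate) neutral losses recognised on glycosides.
# loss_formula is the departing neutral (anhydro form).
sugars:
  - name: hexose
    loss_formula: C6H10O5       # 162.053
  - name: di-hexose
    loss_formula: C12H20O10     # 324.106
  - name: rutinosyl
    loss_formula: C12H20O9      # 308.111
  - name: acetylhexose
    loss_formula: C8H12O6       # 204.063
  - name: caffeoylhexose
    loss_formula: C15H16O8      # 324.085

# Hexose cross-ring cleavages diagnostic of ester-bound sugars; losses in Da
# relative to the precursor.
cross_ring:
  - name: "0,4-Hex"
    loss_formula: C2H4O2        # -60 Da
  - name: "0,3-Hex"
    loss_formula: C3H6O3        # -90 Da
  - name: "0,2-Hex"
    loss_formula: C4H8O4        # -120 Da
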