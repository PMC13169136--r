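# Non-caffeoyl ester substituents recognised on acylhexaric acids.
# acid_formula is the free acid; the residue departs as acid - H2O, so the
# residual mass against the hexarate anion terminus (209.030) is the
# anhydro loss, while ladders terminating at 191.019 correspond to losing
# the full acid.
esters:
  - name: hydroxybutanyl
    acid_formula: C4H8O3      # anhydro loss C4H6O2, 86.037
  - name: hydroxyvaleryl/hydroxyisovaleryl
    acid_formula: C5H10O3     # anhydro loss C5H8O2, 100.052
  - name: butanyl/isobutanyl
    acid_formula: C4H8O2      # anhydro loss C4H6O, 70.042
  - name: methylbutanyl/isovaleryl
    acid_formula: C5H10O2     # anhydro loss C5H8O, 84.058
  - name: hydroxybenzoyl
    acid_formula: C7H6O3      # anhydro loss C7H4O2, 120.021
    markers:
      - { role: acid anion,     formula: C7H6O3 }   # 137.024
      - { role: decarboxylated, formula: C6H6O }    # 93.035
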