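# Acyl residues recognised on quinic (and, where marked, other) backbones.
#
# loss_formula : neutral formula of the residue as it departs (acid - H2O)
# acid_formula : neutral formula of the free acid; its [M-H]- is the primary
#                ("acid anion") marker
# markers      : further diagnostic anions; either a neutral formula whose
#                [M-H]- is the marker, or an explicit m/z
# context      : backbone context in which the residue is considered
#                ("quinic", "glycoside" or "any"); 197.045 means
#                hydroxydihydrocaffeoyl on a quinic backbone but syringoyl in
#                the phenolic-glycoside branch, and is never resolved globally
residues:
  - name: caffeoyl
    loss_formula: C9H6O3
    acid_formula: C9H8O4
    context: any
    markers:
      - role: decarboxylated
        formula: C8H8O2     # [caffeic acid - H - CO2]-, 135.045
      - role: dehydrated
        formula: C9H6O3     # [caffeic acid - H - H2O]-, 161.024
  - name: feruloyl
    loss_formula: C10H8O3
    acid_formula: C10H10O4
    context: any
    markers:
      - role: decarboxylated-demethylated
        mz: 134.0373        # [ferulic acid - H - CO2 - CH3]-.
      - role: decarboxylated
        formula: C9H10O2    # 149.060
  - name: p-coumaroyl
    loss_formula: C9H6O2
    acid_formula: C9H8O3
    context: any
    markers:
      - role: decarboxylated
        formula: C8H8O      # [coumaric acid - H - CO2]-, 119.050
  - name: dihydrocaffeoyl
    loss_formula: C9H8O3
    acid_formula: C9H10O4
    context: quinic
    markers:
      - role: decarboxylated
        formula: C8H10O2    # 137.061
  - name: hydroxydihydrocaffeoyl
    loss_formula: C9H8O4
    acid_formula: C9H10O5
    context: quinic
    markers:
      - role: decarboxylated-dehydrated
        mz: 135.0452        # [acid - H - CO2 - H2O]-
  - name: hydroxybenzoyl
    loss_formula: C7H4O2
    acid_formula: C7H6O3
    context: any
    markers:
      - role: decarboxylated
        formula: C6H6O      # 93.035
  - name: protocatechuoyl
    loss_formula: C7H4O3
    acid_formula: C7H6O4
    context: any
    markers:
      - role: decarboxylated
        formula: C6H6O2     # 109.029
  - name: vanillyl
    loss_formula: C8H6O3
    acid_formula: C8H8O4
    context: any
    markers:
      - role: demethylated
        mz: 152.0115        # [vanillic acid - H - CH3]-.
  - name: syringoyl
    loss_formula: C9H8O4
    acid_formula: C9H10O5
    context: glycoside
    markers:
      - role: demethylated
        mz: 182.0221        # [syringic acid - H - CH3]-.
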