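# Backbone diagnostic-ion series, anchored on theoretical m/z (the series is
# matched at the configured MS2 tolerance, 10 mDa by default; quinic vs
# hexaric hinges on 191.056 vs 191.020, which requires a tolerance < 18 mDa).
backbones:
  - name: quinic
    anion_formula: C7H12O6      # [QA-H]- 191.0561
    series:
      - { formula: C7H12O6, role: "[QA-H]-" }                 # 191.0561
      - { mz: 173.0455,  role: "[QA-H-H2O]-" }
      - { mz: 111.0452,  role: "[QA-H-2H2O-CO2]-" }
      - { mz: 93.0346,   role: "[QA-H-3H2O-CO2]-" }
      - { mz: 85.0295,   role: "[QA-H-2H2O-CO-C2H2O]-" }
  - name: hexaric
    anion_formula: C6H10O8      # [HA-H]- 209.0303
    series:
      - { formula: C6H10O8, role: "[HA-H]-" }                 # 209.0303
      - { mz: 191.0197,  role: "[HA-H-H2O]-" }
      - { mz: 173.0092,  role: "[HA-H-2H2O]-" }
      - { mz: 147.0299,  role: "[HA-H-H2O-CO2]-" }
      - { mz: 129.0193,  role: "[HA-H-2H2O-CO2]-" }
      - { mz: 111.0088,  role: "[HA-H-3H2O-CO2]-" }
      - { mz: 85.0295,   role: "[HA-H-2H2O-2CO2]-" }
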