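# Default postcolumn-infusion standards panel: eight isotopically labelled
# drugs spanning a broad polarity range, with the infusion-solution
# concentrations (mg/L) at which each was optimised to sit above background
# noise without self-suppression. Formulas use D for deuterium and [13C]
# bracket notation for carbon-13 labels.
version: pciqc-default-1
standards:
  - name: metformin-d6
    formula: C4H5D6N5
    adducts: ["[M+H]+"]
    infusion_conc_mg_per_L: 0.030
  - name: atenolol-d7
    formula: C14H15D7N2O3
    adducts: ["[M+H]+"]
    infusion_conc_mg_per_L: 0.025
  - name: acetaminophen-d4
    formula: C8H5D4NO2
    adducts: ["[M+H]+"]
    infusion_conc_mg_per_L: 0.25
  - name: caffeine-d3
    formula: C8H7D3N4O2
    adducts: ["[M+H]+"]
    infusion_conc_mg_per_L: 0.125
  - name: nifedipine-d6
    formula: C17H12D6N2O6
    adducts: ["[M+H]+"]
    infusion_conc_mg_per_L: 0.125
  - name: diclofenac-13C6
    formula: C8[13C]6H11Cl2NO2
    adducts: ["[M+H]+"]
    infusion_conc_mg_per_L: 0.25
  - name: lacidipine-13C8
    formula: C18[13C]8H33NO6
    adducts: ["[M+H]+"]
    infusion_conc_mg_per_L: 0.030
  - name: simvastatin-d6
    formula: C25H32D6O5
    adducts: ["[M+H]+", "[M+Na]+", "[M+K]+"]
    infusion_conc_mg_per_L: 0.125
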