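# Default analyte panel for the 17-element PTE survey.
# MDL (ug/L) and error_fraction values are SYNTHETIC PLACEHOLDERS of
# realistic magnitude: replace them with your laboratory's reported
# detection limits and error fractions before analysing real data.
# drinking_limit (ug/L) is bundled only for Hg, As, Se and Cd; supply
# the remaining limits from the standard applicable to your study area.
analytes:
  - {name: Fe, mdl: 10,   error_fraction: 0.10}
  - {name: Mn, mdl: 1,    error_fraction: 0.10}
  - {name: Cu, mdl: 0.5,  error_fraction: 0.10}
  - {name: Zn, mdl: 1,    error_fraction: 0.10}
  - {name: Al, mdl: 10,   error_fraction: 0.10}
  - {name: Hg, mdl: 0.04, error_fraction: 0.15, drinking_limit: 1}
  - {name: As, mdl: 0.3,  error_fraction: 0.12, drinking_limit: 10}
  - {name: Se, mdl: 0.4,  error_fraction: 0.12, drinking_limit: 10}
  - {name: Cd, mdl: 0.05, error_fraction: 0.10, drinking_limit: 5}
  - {name: Pb, mdl: 0.09, error_fraction: 0.12}
  - {name: Li, mdl: 0.3,  error_fraction: 0.10}
  - {name: B,  mdl: 5,    error_fraction: 0.10}
  - {name: Ba, mdl: 1,    error_fraction: 0.10}
  - {name: Sb, mdl: 0.15, error_fraction: 0.15}
  - {name: Ni, mdl: 0.6,  error_fraction: 0.10}
  - {name: Co, mdl: 0.03, error_fraction: 0.10}
  - {name: Mo, mdl: 0.06, error_fraction: 0.10}
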