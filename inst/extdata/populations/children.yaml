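# Children (7 years). Liver weight is the reference value for this age
# group; MPPGL, fu_p, GFR and enzyme abundances are SYNTHETIC placeholders
# equal to the adult values and must be replaced before quantitative use.
label: children
age_years: 7
weight_kg: 23
liver_weight_g: 726.23
MPPGL: 38
GFR: 120
GFR_unit: mL/min
fu_p: 0.45
enzyme_abundance:
  UGT1A3: {mean: 25.01}
  UGT1A4: {mean: 46.77}
provenance: liver weight age-specific; other fields synthetic placeholder (equal to adult)
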