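# Hepatic impairment, Child-Pugh C, alcoholic cirrhosis (30 years).
# Liver weight is the reference Child-Pugh C value; UGT1A4 abundance is
# 12-fold lower than the healthy-adult mean (alcoholic-cirrhosis livers).
# MPPGL, fu_p and GFR are SYNTHETIC placeholders equal to the adult values.
# Kept separate from the HCV-cirrhosis spec: the two aetiologies carry
# distinct scale factors and must never be conflated.
label: hi_child_pugh_c_alcoholic
age_years: 30
weight_kg: 70
liver_weight_g: 867.97
MPPGL: 38
GFR: 120
GFR_unit: mL/min
fu_p: 0.45
enzyme_abundance:
  UGT1A4: {mean: 3.8975}   # 46.77 / 12
provenance: UGT1A4 alcoholic cirrhosis (12-fold reduction); MPPGL/fu_p/GFR synthetic placeholder (equal to adult)
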