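# Healthy adult reference population. Enzyme abundances are the pooled
# weighted means with method-II geometric 95% bounds.
label: adult
age_years: 30
weight_kg: 70
liver_weight_g: 1637.7
MPPGL: 38
GFR: 120
GFR_unit: mL/min
fu_p: 0.45
enzyme_abundance:
  UGT1A3: {mean: 25.01, low: 8.30, high: 75.33}
  UGT1A4: {mean: 46.77, low: 30.88, high: 70.82}
provenance: adult reference (pooled liver-microsome abundances, method II bounds)
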