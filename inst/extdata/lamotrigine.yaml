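# Lamotrigine drug parameters for the IVIVE chain.
# CL_H is derived as (1 - f_CL_renal) * CL_IV; CL_R as f_CL_renal * CL_IV.
CL_IV: 2          # L/h, intravenous plasma clearance
f_CL_renal: 0.10  # fraction cleared unchanged renally
fu_p: 0.45        # unbound fraction in plasma
BP: 1             # blood:plasma concentration ratio
fu_mic: 1         # unbound fraction in microsomal incubation
# Fractions metabolized: glucuronidation (0.86 of total clearance) split
# 10%/90% between UGT1A3 and UGT1A4; minor oxidative (CYP) pathway 0.04.
f_m:
  UGT:
    total: 0.86
    split:
      UGT1A3: 0.10
      UGT1A4: 0.90
  CYP: 0.04
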