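# Lamotrigine-metabolizing UGT isoforms: kinetic constants and default
# adult liver-microsomal abundances.
enzyme,f_m,Km_uM,abundance_pmol_per_mg,ISEF
UGT1A3,0.086,70,7.6,1
UGT1A4,0.774,550,7.9,1
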