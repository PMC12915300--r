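label,substrate,formula,conc_M,coef_so4,coef_h,coef_co2,coef_h2s,coef_nh4,coef_h2o,dg0_per_c_kj,dgprime_per_c_kj,note
R1,Alanine,C2H5NO2,2.5e-3,0.75,2.5,2,0.75,1,1,-167,-153,label/formula swap as printed (formula is glycine)
R2,Glycine,C3H7NO2,2.5e-3,1.5,4,3,1.5,2,2,-171,-165,as printed; not element/charge balanced (2 NH4+ for one N)
R3,Glucose,C6H12O6,2.5e-3,3,6,6,3,0,6,-121,-118,
R4,Galactose,C6H12O6,2.5e-3,3,6,6,3,0,6,-141,-137,same formula as R3; printed dG0 differs by 20 kJ/mol C
R5,Palmitate,C18H33O2-,1e-3,12.75,26.5,18,12.75,0,17,-106,-97.1,label/formula swap as printed (formula is oleate)
R6,Oleate,C16H31O2-,1e-3,11.5,24,16,11.5,0,16,-97.3,-88.4,label/formula swap as printed (formula is palmitate)
R7,Glycerol,C3H8O3,5e-3,1.75,3.5,3,1.75,0,4,-146,-136,
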