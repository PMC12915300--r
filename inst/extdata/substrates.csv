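name,cod_dose_mg_l,mass_dose_g_l,conc_mM,formula,starch_pct,protein_pct,fat_pct,fiber_pct,c_pct,n_pct,s_pct,p_pct,fe_mg_kg,na_mg_kg,dose_provenance
Coccomyxa,494,0.38,,,1.1,48,6.7,0.2,50,7.7,0.40,2.1,2190,217,stated
Euglena,494,0.489,,,4.3,15,6.2,0.1,43,2.3,0.13,1.1,35,950,back_computed
Duckweed,494,0.592,,,9.6,16,3.3,17,34,2.1,0.43,1.3,2410,8340,back_computed
Glycerol,494,,5,C3H8O3,,,,,,,,,,,stated
Casamino acids,494,,,,,,,,,,,,,,stated
Glucose,414,,2.5,C6H12O6,,,,,,,,,,,stated
Galactose,426,,2.5,C6H12O6,,,,,,,,,,,stated
Palmitate,264,,1,C16H31O2-,,,,,,,,,,,stated
Oleate,744,,1,C18H33O2-,,,,,,,,,,,stated
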