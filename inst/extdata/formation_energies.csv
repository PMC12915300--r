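species,dgf_kj_mol,state,provenance
H2O,-237.18,liquid,standard compilation
CO2(g),-394.36,gas,standard compilation
SO4^2-,-744.53,aqueous,standard compilation
H+,0,aqueous,convention
H2S(aq),-27.83,aqueous,standard compilation
NH4+,-79.31,aqueous,standard compilation
C6H12O6,-915.9,aqueous,standard compilation (glucose)
C3H8O3,-488.52,aqueous,standard compilation (glycerol)
C2H5NO2,-370.79,aqueous,standard compilation (glycine)
C3H7NO2,-371.0,aqueous,standard compilation (alanine)
C16H31O2-,-288,aqueous,estimate (group additivity; synthetic stand-in)
C18H33O2-,-245,aqueous,estimate (group additivity; synthetic stand-in)
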