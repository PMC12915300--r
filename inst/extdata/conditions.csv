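quantity,kind,value,units
temperature,state,291,K
pH,state,4.2,
CO2(g),activity,0.05,atm
SO4^2-,activity,0.14,M
NH4+,activity,0.01,M
H2S(aq),activity,1e-6,M
C6H12O6,activity,2.5e-3,M
C2H5NO2,activity,2.5e-3,M
C3H7NO2,activity,2.5e-3,M
C3H8O3,activity,5e-3,M
C18H33O2-,activity,1e-3,M
C16H31O2-,activity,1e-3,M
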