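name	density_g_cm3	Z_over_A	I_eV	X0_g_cm2	composition
air	0.0012048	0.49919	85.7	36.62	C:0.000124,N:0.755267,O:0.231781,Ar:0.012828
water	1.000	0.55509	75.0	36.08	H:0.111894,O:0.888106
polyethylene	0.950	0.57034	57.4	44.77	H:0.143711,C:0.856289
pmma	1.180	0.53937	74.0	40.55	H:0.080538,C:0.599848,O:0.319614
polyvinyltoluene	1.032	0.54141	64.7	43.79	H:0.085000,C:0.915000
silicon	2.330	0.49848	173.0	21.82	Si:1.0
gold	19.320	0.40108	790.0	6.46	Au:1.0
platinum	21.450	0.39984	790.0	6.54	Pt:1.0
zro2	5.680	0.45450	261.0	11.03	Zr:0.740300,O:0.259700
fr4	1.850	0.52000	110.0	28.50	H:0.030000,C:0.300000,O:0.390000,Si:0.180000,Ca:0.060000,Al:0.040000
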