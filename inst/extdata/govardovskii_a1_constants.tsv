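constant	band	value	unit
A	alpha	69.7	dimensionless
B	alpha	28	dimensionless
C	alpha	-14.9	dimensionless
D	alpha	0.674	dimensionless
b	alpha	0.922	dimensionless
c	alpha	1.104	dimensionless
a0	alpha	0.8795	dimensionless
a1	alpha	0.0459	dimensionless
a_width	alpha	11940	nm^2
A_beta	beta	0.26	dimensionless
beta_pos_intercept	beta	189	nm
beta_pos_slope	beta	0.315	dimensionless
beta_width_intercept	beta	-40.5	nm
beta_width_slope	beta	0.195	dimensionless
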