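# Carbon-on-hydrogen non-elastic cross-section knots, SYNTHETIC:
# a smooth approximation to the inverse-kinematics proton-on-carbon
# reaction cross-section (broad low-energy maximum, shallow minimum
# near 200 MeV/u, nearly constant plateau above 250 MeV/u).
# Constructed for this package; not a published data set.
# E in MeV/u, sigma in mb.
E	sigma
10	450
20	420
30	375
40	340
60	290
80	250
100	230
150	205
200	200
250	210
300	214
350	216
400	217
450	217
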