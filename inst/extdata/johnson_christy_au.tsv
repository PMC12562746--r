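# Complex refractive index of evaporated gold films.
# Transcribed from the Johnson & Christy (1972) tabulation; photon energies
# 0.64-2.13 eV converted to vacuum wavelength (lambda_um = 1.239842/E_eV).
# Columns: lambda_um  n  k
# provenance: Johnson-Christy-1972-Au (transcribed)
0.5821	0.29	2.863
0.6168	0.21	3.272
0.6595	0.14	3.697
0.7045	0.13	4.103
0.7560	0.14	4.542
0.8211	0.16	5.083
0.8920	0.17	5.663
0.9840	0.22	6.350
1.0876	0.27	7.150
1.2155	0.35	8.145
1.3931	0.43	9.519
1.6102	0.56	11.21
1.9373	0.92	13.78
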