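# Complex refractive index of evaporated copper films.
# Transcribed from the Johnson & Christy (1972) tabulation; photon energies
# 0.64-2.13 eV converted to vacuum wavelength (lambda_um = 1.239842/E_eV).
# Columns: lambda_um  n  k
# provenance: Johnson-Christy-1972-Cu (transcribed)
0.5821	0.70	2.704
0.6168	0.30	3.205
0.6595	0.22	3.747
0.7045	0.21	4.205
0.7560	0.24	4.665
0.8211	0.26	5.180
0.8920	0.30	5.768
0.9840	0.32	6.421
1.0876	0.36	7.217
1.2155	0.48	8.245
1.3931	0.60	9.439
1.6102	0.76	11.12
1.9373	1.09	13.43
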