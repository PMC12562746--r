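# Complex refractive index of evaporated silver films.
# Transcribed from the Johnson & Christy (1972) tabulation; photon energies
# 0.64-2.13 eV converted to vacuum wavelength (lambda_um = 1.239842/E_eV).
# Columns: lambda_um  n  k
# provenance: Johnson-Christy-1972-Ag (transcribed)
0.5821	0.05	3.858
0.6168	0.06	4.152
0.6595	0.05	4.483
0.7045	0.04	4.838
0.7560	0.03	5.242
0.8211	0.04	5.727
0.8920	0.04	6.312
0.9840	0.04	6.992
1.0876	0.04	7.795
1.2155	0.09	8.828
1.3931	0.13	10.10
1.6102	0.15	11.85
1.9373	0.24	14.08
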