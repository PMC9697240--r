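# Fiber-model helix parameters, version 1.0
# Uniform base-step rigid-body coordinates and sugar descriptors used by the
# fiber-model generator for the two canonical right-handed DNA families, as
# established by fiber-diffraction work on calf-thymus (B form) and
# low-humidity (A form) DNA.  Translations in Angstrom, angles in degrees.
# B form: 36-degree twist and 3.38 A rise with vanishing slide/roll (ten
# residues per turn; helical rise equals rise), C2'-endo sugars, anti chi.
# A form: 32.7-degree twist with negative slide and positive roll, which
# tilts base planes away from the helix axis so the helical rise (~2.6 A)
# falls well below the stacking rise; C3'-endo sugars.
# pucker_P / pucker_tau: pseudorotation phase and amplitude of the sugar
# template; chi: glycosidic torsion O4'-C1'-N9-C4 (purines) or
# O4'-C1'-N1-C2 (pyrimidines) used when anchoring the sugar; delta:
# backbone torsion C5'-C4'-C3'-O3' used when placing O3' (follows the
# pucker family: ~140 deg for C2'-endo, ~83 deg for C3'-endo).
# Columns: form shift slide rise tilt roll twist pucker_P pucker_tau chi delta
form	shift	slide	rise	tilt	roll	twist	pucker_P	pucker_tau	chi	delta
B	0.0	0.0	3.38	0.0	0.0	36.0	162.0	36.0	-105.0	140.0
A	0.0	-1.50	3.30	0.0	12.0	32.7	18.0	40.0	-160.0	83.0
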