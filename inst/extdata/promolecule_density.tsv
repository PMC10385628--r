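# Spherically averaged atomic electron densities as sums of exponential
# shells: rho_elem(r) = sum_k c_k exp(-z_k r), with c_k = n_k z_k^3 / (8 pi)
# so each shell integrates exactly to its n_k electrons.
# Decay constants z (1/angstrom) are 2*zeta/a0 from Slater-screened effective
# nuclear charges (Slater 1930, Phys Rev 36:57), zeta = Zeff/n*, a0 = 0.529177
# angstrom; the hydrogen entry is the exact ground-state 1s density.
# n: electrons in the shell; z: radial decay constant (1/angstrom).
element	n	z
H	1	3.779452
C	2	21.542878
C	4	6.141860
N	2	25.322331
N	5	7.370432
O	2	29.101784
O	6	8.599003
P	2	55.557890
P	8	20.503529
P	5	6.047124
S	2	59.337343
S	8	22.393367
S	6	6.866079
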