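# Published chemical composition of the Hirshfeld interface between the PPR
# moiety of the KDKPPR peptide (side a, "peptide") and the neuropilin-1 b1
# domain including four structural waters (side b, "protein"), for the
# deposited crystal structure of the hexavariant complex (PDB 8PFE).
# block "surface": percent of interface area per chemical type and side.
# block "contacts": observed contact proportions C_XY, percent of interface
# area per unordered type pair. One-decimal printed precision.
block	row	col	value
surface	peptide	C	8.8
surface	peptide	Hc	42.7
surface	peptide	N	5.5
surface	peptide	Ho/n	22.9
surface	peptide	O	20.1
surface	peptide	W	0
surface	protein	C	21.4
surface	protein	Hc	30.0
surface	protein	N	1.2
surface	protein	Ho/n	15.6
surface	protein	O	15.9
surface	protein	W	16.0
contacts	C	C	1.4
contacts	C	Hc	21.3
contacts	C	N	1.3
contacts	C	Ho/n	3.4
contacts	C	O	0.4
contacts	C	W	1.0
contacts	Hc	Hc	10.3
contacts	Hc	N	3.5
contacts	Hc	Ho/n	7.2
contacts	Hc	O	15.3
contacts	Hc	W	4.8
contacts	N	N	0
contacts	N	Ho/n	0.5
contacts	N	O	0.2
contacts	N	W	1.3
contacts	Ho/n	Ho/n	1.6
contacts	Ho/n	O	17.4
contacts	Ho/n	W	6.9
contacts	O	O	0.3
contacts	O	W	2.0
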