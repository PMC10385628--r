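# Ionizable-group pKa values for isoelectric-point estimation.
# set "emboss": the table distributed with the EMBOSS `iep` program
# (Rice et al. 2000, Trends Genet 16:276-277). sign: +1 basic, -1 acidic.
set	group	pka	sign
emboss	Nterm	8.6	1
emboss	Cterm	3.6	-1
emboss	K	10.8	1
emboss	R	12.5	1
emboss	H	6.5	1
emboss	D	3.9	-1
emboss	E	4.1	-1
emboss	C	8.5	-1
emboss	Y	10.1	-1
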