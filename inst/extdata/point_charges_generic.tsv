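# Generic point-charge set for interaction-type classes, written for this
# package (synthetic; magnitudes loosely follow common biomolecular force
# fields: amide/carboxylate-scale polar charges, near-neutral aliphatics).
# Matching columns use "*" as a wildcard; more specific rows win.
# Charges in elementary units.
resname	name	type	element	charge
*	*	C	*	0.05
*	*	Hc	*	0.09
*	*	N	*	-0.45
*	*	Ho/n	*	0.35
*	*	O	*	-0.55
*	*	W	*	-0.80
*	*	*	H	0.09
*	*	*	C	0.05
*	*	*	N	-0.45
*	*	*	O	-0.55
*	*	*	S	-0.10
*	*	*	P	0.80
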