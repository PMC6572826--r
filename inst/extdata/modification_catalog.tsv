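# Default modification/adduct catalog (UNIMOD-style subset).
# delta_formula: Hill notation with signed counts; for adducts it is the bare
# cation composition and protons_displaced gives the number of protons the
# cation replaces (net neutral shift = mass(formula) - protons_displaced * H).
name	delta_formula	terminal_specificity	residue_specificity	category	protons_displaced
NtAc	C2H2O1	N-term	.	PTM	0
Met_OFF	C-5H-9N-1O-1S-1	N-term	M	processing	0
Methyl	C1H2	none	.	PTM	0
Cu(II)	Cu1	none	.	adduct	2
Zn(II)	Zn1	none	.	adduct	2
NH4	N1H4	none	.	adduct	1
Na	Na1	none	.	adduct	1
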