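# IUPAC conventional standard atomic weights (Da)
element	average_mass
H	1.008
C	12.011
N	14.007
O	15.999
S	32.06
P	30.973762
Na	22.98976928
K	39.0983
Fe	55.845
Cu	63.546
Zn	65.38
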