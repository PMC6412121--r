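# Synthetic benchmark site set for the U1-like / U2-like molecules in
# snrna_like.fasta.  Stoichiometries (fractions) define the simulated
# control and knockdown conditions; `enzyme` is the digest that reads
# the site out, `method` its designated estimator, and `bio_sd` the
# between-replicate biological SD of the true stoichiometry.
molecule_id	position	mod_type	site	enzyme	method	guide	control	knockdown	bio_sd
U1	70	2'-O-methyl	U1-70Am	RNaseT1	silnas	scaRNA7	0.793	0.242	0.0537
U2	1	2'-O-methyl	U2-1Am(cap)	RNaseA	peak_area	-	0.993	0.991	0.0025
U2	11	2'-O-methyl	U2-11Gm	RNaseA	peak_area	scaRNA2	0.953	0.926	0.0372
U2	12	2'-O-methyl	U2-12Gm	RNaseA	peak_area	unknown	0.962	0.938	0.0312
U2	19	2'-O-methyl	U2-19Gm	RNaseT1	silnas	scaRNA9	0.765	0.477	0.0329
U2	25	2'-O-methyl	U2-25Gm	RNaseA	silnas	scaRNA2	0.980	0.339	0.0554
U2	30	2'-O-methyl	U2-30Am	RNaseA	peak_area	scaRNA9	0.948	0.909	0.0490
U2	34	pseudouridine	U2-34Y	RNaseT1	silnas	scaRNA8	0.840	0.795	0.0987
U2	40	2'-O-methyl	U2-40Cm	RNaseT1	peak_area	unknown	0.951	0.737	0.0390
U2	47	2'-O-methyl	U2-47Um	RNaseT1	peak_area	scaRNA28	0.956	0.271	0.0234
U2	61	2'-O-methyl	U2-61Cm	RNaseT1	peak_area	scaRNA2	0.572	0.206	0.0892
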