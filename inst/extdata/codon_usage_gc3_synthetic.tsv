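codon	amino_acid	relative_frequency
TTT	F	0.2
TTC	F	0.8
TTA	L	0.0666666666666667
TTG	L	0.266666666666667
TCT	S	0.0666666666666667
TCC	S	0.266666666666667
TCA	S	0.0666666666666667
TCG	S	0.266666666666667
TAT	Y	0.2
TAC	Y	0.8
TGT	C	0.2
TGC	C	0.8
TGG	W	1
CTT	L	0.0666666666666667
CTC	L	0.266666666666667
CTA	L	0.0666666666666667
CTG	L	0.266666666666667
CCT	P	0.1
CCC	P	0.4
CCA	P	0.1
CCG	P	0.4
CAT	H	0.2
CAC	H	0.8
CAA	Q	0.2
CAG	Q	0.8
CGT	R	0.0666666666666667
CGC	R	0.266666666666667
CGA	R	0.0666666666666667
CGG	R	0.266666666666667
ATT	I	0.166666666666667
ATC	I	0.666666666666667
ATA	I	0.166666666666667
ATG	M	1
ACT	T	0.1
ACC	T	0.4
ACA	T	0.1
ACG	T	0.4
AAT	N	0.2
AAC	N	0.8
AAA	K	0.2
AAG	K	0.8
AGT	S	0.0666666666666667
AGC	S	0.266666666666667
AGA	R	0.0666666666666667
AGG	R	0.266666666666667
GTT	V	0.1
GTC	V	0.4
GTA	V	0.1
GTG	V	0.4
GCT	A	0.1
GCC	A	0.4
GCA	A	0.1
GCG	A	0.4
GAT	D	0.2
GAC	D	0.8
GAA	E	0.2
GAG	E	0.8
GGT	G	0.1
GGC	G	0.4
GGA	G	0.1
GGG	G	0.4
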