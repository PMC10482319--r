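codon	weight
AAA	0.5
AAC	0.5
AAG	1
AAT	1
ACA	0.25
ACC	0.5
ACG	0.75
ACT	1
AGA	0.166666666666667
AGC	0.166666666666667
AGG	0.333333333333333
AGT	0.333333333333333
ATA	0.333333333333333
ATC	0.666666666666667
ATG	1
ATT	1
CAA	0.5
CAC	0.5
CAG	1
CAT	1
CCA	0.25
CCC	0.5
CCG	0.75
CCT	1
CGA	0.5
CGC	0.666666666666667
CGG	0.833333333333333
CGT	1
CTA	0.166666666666667
CTC	0.333333333333333
CTG	0.5
CTT	0.666666666666667
GAA	0.5
GAC	0.5
GAG	1
GAT	1
GCA	0.25
GCC	0.5
GCG	0.75
GCT	1
GGA	0.25
GGC	0.5
GGG	0.75
GGT	1
GTA	0.25
GTC	0.5
GTG	0.75
GTT	1
TAC	0.5
TAT	1
TCA	0.5
TCC	0.666666666666667
TCG	0.833333333333333
TCT	1
TGC	0.5
TGG	1
TGT	1
TTA	0.833333333333333
TTC	0.5
TTG	1
TTT	1
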