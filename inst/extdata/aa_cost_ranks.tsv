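amino_acid	cost_rank
Trp	1
Phe	2
Tyr	3
His	4
Met	5
Ile	6
Lys	7
Arg	8
Leu	9
Cys	10
Val	11
Pro	12
Thr	13
Gln	14
Glu	15
Asn	16
Asp	17
Ala	18
Gly	19
Ser	20
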