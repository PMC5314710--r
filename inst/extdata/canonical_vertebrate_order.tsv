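# Canonical vertebrate mitochondrial gene order, linearized at tRNA-Phe.
# 37 loci: 13 protein-coding genes, 2 rRNAs, 22 tRNAs (two Ser, two Leu copies).
# Strand: +1 heavy, -1 light. typical_bp: representative vertebrate lengths,
# used by the synthetic genome generator (CDS lengths are multiples of 3).
# The arrangement (incl. Ile(+)/Gln(-)/Met(+), His/Ser/Leu block, ND6 and
# tRNA-Pro on the light strand) is the shared vertebrate consensus seen in
# human, mouse, Xenopus and most teleost mitogenomes.
locus	feature_class	strand	typical_bp
Phe	tRNA	1	69
rrnS	rRNA	1	954
Val	tRNA	1	69
rrnL	rRNA	1	1677
LeuUUR	tRNA	1	75
ND1	CDS	1	957
Ile	tRNA	1	69
Gln	tRNA	-1	72
Met	tRNA	1	69
ND2	CDS	1	1044
Trp	tRNA	1	69
Ala	tRNA	-1	69
Asn	tRNA	-1	73
Cys	tRNA	-1	66
Tyr	tRNA	-1	70
COX1	CDS	1	1551
SerUCN	tRNA	-1	72
Asp	tRNA	1	69
COX2	CDS	1	690
Lys	tRNA	1	70
ATP8	CDS	1	168
ATP6	CDS	1	684
COX3	CDS	1	786
Gly	tRNA	1	69
ND3	CDS	1	348
Arg	tRNA	1	69
ND4L	CDS	1	297
ND4	CDS	1	1380
His	tRNA	1	69
SerAGY	tRNA	1	67
LeuCUN	tRNA	1	73
ND5	CDS	1	1839
ND6	CDS	-1	522
Glu	tRNA	-1	69
CYTB	CDS	1	1140
Thr	tRNA	1	72
Pro	tRNA	-1	69
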