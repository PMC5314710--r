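# Name-normalization table mapping annotation spellings to canonical locus ids.
# Matching is case-insensitive after stripping spaces, hyphens, underscores
# and parentheses. Edit or extend to accommodate other annotation pipelines.
synonym	locus
trnF	Phe
tRNA-Phe	Phe
tRNAPhe	Phe
phenylalanine	Phe
trnV	Val
tRNA-Val	Val
valine	Val
trnL(UUR)	LeuUUR
trnL2	LeuUUR
tRNA-Leu(UUR)	LeuUUR
tRNA-Leu2	LeuUUR
trnL(CUN)	LeuCUN
trnL1	LeuCUN
tRNA-Leu(CUN)	LeuCUN
tRNA-Leu1	LeuCUN
trnI	Ile
tRNA-Ile	Ile
isoleucine	Ile
trnQ	Gln
tRNA-Gln	Gln
glutamine	Gln
trnM	Met
tRNA-Met	Met
methionine	Met
trnW	Trp
tRNA-Trp	Trp
trnA	Ala
tRNA-Ala	Ala
trnN	Asn
tRNA-Asn	Asn
trnC	Cys
tRNA-Cys	Cys
trnY	Tyr
tRNA-Tyr	Tyr
trnS(UCN)	SerUCN
trnS2	SerUCN
tRNA-Ser(UCN)	SerUCN
tRNA-Ser2	SerUCN
trnS(AGY)	SerAGY
trnS1	SerAGY
tRNA-Ser(AGY)	SerAGY
tRNA-Ser1	SerAGY
trnD	Asp
tRNA-Asp	Asp
trnK	Lys
tRNA-Lys	Lys
trnG	Gly
tRNA-Gly	Gly
trnR	Arg
tRNA-Arg	Arg
trnH	His
tRNA-His	His
histidine	His
trnE	Glu
tRNA-Glu	Glu
trnT	Thr
tRNA-Thr	Thr
trnP	Pro
tRNA-Pro	Pro
proline	Pro
12S	rrnS
12S rRNA	rrnS
12S ribosomal RNA	rrnS
s-rRNA	rrnS
small subunit ribosomal RNA	rrnS
rrn12	rrnS
MT-RNR1	rrnS
16S	rrnL
16S rRNA	rrnL
16S ribosomal RNA	rrnL
l-rRNA	rrnL
large subunit ribosomal RNA	rrnL
rrn16	rrnL
MT-RNR2	rrnL
ND1	ND1
NADH dehydrogenase subunit 1	ND1
nad1	ND1
ND2	ND2
NADH dehydrogenase subunit 2	ND2
nad2	ND2
ND3	ND3
NADH dehydrogenase subunit 3	ND3
nad3	ND3
ND4	ND4
NADH dehydrogenase subunit 4	ND4
nad4	ND4
ND4L	ND4L
NADH dehydrogenase subunit 4L	ND4L
nad4l	ND4L
ND5	ND5
NADH dehydrogenase subunit 5	ND5
nad5	ND5
ND6	ND6
NADH dehydrogenase subunit 6	ND6
nad6	ND6
COX1	COX1
COI	COX1
cox1	COX1
cytochrome c oxidase subunit I	COX1
cytochrome c oxidase subunit 1	COX1
COX2	COX2
COII	COX2
cox2	COX2
cytochrome c oxidase subunit II	COX2
cytochrome c oxidase subunit 2	COX2
COX3	COX3
COIII	COX3
cox3	COX3
cytochrome c oxidase subunit III	COX3
cytochrome c oxidase subunit 3	COX3
ATP6	ATP6
atp6	ATP6
ATPase subunit 6	ATP6
ATP synthase F0 subunit 6	ATP6
ATP8	ATP8
atp8	ATP8
ATPase subunit 8	ATP8
ATP synthase F0 subunit 8	ATP8
CYTB	CYTB
cob	CYTB
cytb	CYTB
cytochrome b	CYTB
D-loop	noncoding
control region	noncoding
misc_feature	noncoding
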