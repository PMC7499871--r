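# Drug-alteration knowledge table for lung cancer actionability matching,
# transcribed from the curated evidence assignments used by the cohort
# analysis (CIViC / OncoKB-style levels: A/B = tier 1 guideline or trial
# evidence, C/D = tier 2 case-study or preclinical evidence).
# pattern_kind: exact = exact protein label; class = label class
# (truncating covers trailing-X nonsense and fs frameshift labels);
# amplification / fusion match gene-level events.
gene	pattern	pattern_kind	drug	level	tier	note
EGFR	E746_A750delELREA	exact	Gefitinib	A	1	first-line TKI for exon 19 deletion
EGFR	L747_A750delinsP	exact	Gefitinib	A	1	first-line TKI for exon 19 indel
EGFR	L858R	exact	Gefitinib	A	1	first-line TKI option
EGFR	L858R	exact	Erlotinib	A	1	first-line TKI option
EGFR	L858R	exact	Osimertinib	A	1	first-line TKI option
EGFR	L861Q	exact	Gefitinib	A	1	uncommon activating mutation
EGFR	G719S	exact	Osimertinib	B	1	uncommon activating mutation
EGFR	amplification	amplification	Erlotinib	B	1	more effective than gefitinib for driver amplification
ALK	fusion	fusion	Crizotinib	A	1	ALK fusion TKI
TP53	truncating	class	AZD1775	D	2	WEE1 inhibitor, p53-deficient tumors
TP53	R248W	exact	AZD1775	D	2	WEE1 inhibitor, p53 missense hotspot
ATM	truncating	class	Olaparib	D	2	PARP inhibitor, ATM loss
CDK4	amplification	amplification	Abemaciclib	B	1	CDK4/6 inhibitor (non-lung evidence)
FGFR1	amplification	amplification	Dovitinib	D	2	FGFR inhibitor
FGFR3	R248C	exact	Dovitinib	D	2	FGFR inhibitor
KRAS	G12D	exact	Cobimetinib	D	2	MEK inhibitor
KRAS	G12C	exact	AMG-510	B	1	KRAS G12C inhibitor
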