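# Treatable genetic variants per patient with drug options and evidence
# levels. One row per (patient, gene, event) as reported; labels are the
# published protein-level labels, printed_* are the parenthetical numbers
# printed beside each label (mutation copy number for SNVs/indels, fusion
# fraction for fusions), verbatim and uninterpreted. For amplification
# events pt_cn / bm_cn are the observed gene copy numbers the pipeline
# consumes; entries printed as the rounded integer 5 alongside an
# amplification flag (strict > 5 rule) are stored as synthetic
# pre-rounding values (5.3 / 5.4) consistent with that flag.
# alternative = TRUE marks options beyond the initially administered
# therapy (bold in the published table).
patient_id	gene	event_kind	variant_type	pt_label	pt_printed	bm_label	bm_printed	pt_cn	bm_cn	drug	level	alternative
P1	EGFR	mutation	indel	E746_A750delELREA	1	E746_A750delELREA	1	NA	NA	Gefitinib	A	FALSE
P2	EGFR	mutation	indel	E746_A750delELREA	1	E746_A750delELREA	2	NA	NA	Gefitinib	A	FALSE
P3	EGFR	mutation	indel	E746_A750delELREA	6	E746_A750delELREA	5	NA	NA	Gefitinib	A	FALSE
P3	EGFR	amplification	NA	amplification	NA	amplification	NA	6	5.4	Erlotinib	B	TRUE
P4	EGFR	mutation	indel	L747_A750delinsP	1	L747_A750delinsP	1	NA	NA	Gefitinib	A	FALSE
P5	EGFR	mutation	indel	E746_A750delELREA	0.1	E746_A750delELREA	2	NA	NA	Gefitinib	A	FALSE
P6	EGFR	mutation	indel	E746_A750delELREA	1	E746_A750delELREA	9	NA	NA	Gefitinib	A	FALSE
P6	EGFR	amplification	NA	negative	NA	amplification	NA	1	9	Erlotinib	B	TRUE
P6	TP53	mutation	snv	negative	NA	Q331X	2	NA	NA	AZD1775	D	TRUE
P7	EGFR	mutation	snv	L858R	2	L858R	3	NA	NA	Gefitinib	A	FALSE
P8	EGFR	mutation	snv	L858R	5	L858R	4	NA	NA	Gefitinib	A	FALSE
P9	EGFR	mutation	snv	L858R	5	L858R	6	NA	NA	Erlotinib	A	FALSE
P9	EGFR	amplification	NA	amplification	NA	amplification	NA	5.4	6	Erlotinib	B	FALSE
P9	ATM	mutation	snv	W3052X	2	W3052X	2	NA	NA	Olaparib	D	TRUE
P10	EGFR	mutation	snv	negative	NA	L858R	4	NA	NA	Osimertinib	A	FALSE
P10	CDK4	amplification	NA	negative	NA	amplification	17	2	17	Abemaciclib	B	TRUE
P11	EGFR	mutation	snv	negative	NA	L858R	2	NA	NA	Gefitinib	A	FALSE
P12	EGFR	mutation	snv	G719S	5	G719S	5	NA	NA	Osimertinib	B	FALSE
P12	EGFR	amplification	NA	amplification	NA	amplification	NA	5.4	5.3	Erlotinib	B	TRUE
P12	TP53	mutation	snv	R196X	2	R196X	2	NA	NA	AZD1775	D	TRUE
P13	EGFR	mutation	snv	L861Q	2	L861Q	3	NA	NA	Gefitinib	A	FALSE
P13	TP53	mutation	snv	R248W	2	R248W	2	NA	NA	AZD1775	D	TRUE
P14	ALK	fusion	fusion	Fusion	0.3	Fusion	0.2	NA	NA	Crizotinib	A	FALSE
P15	TP53	mutation	indel	F134Pfs	1	F134Pfs	1	NA	NA	AZD1775	D	TRUE
P15	FGFR1	amplification	NA	amplification	5	amplification	6	5.4	6	Dovitinib	D	TRUE
P16	FGFR3	mutation	snv	R248C	0.1	negative	NA	NA	NA	Dovitinib	D	TRUE
P16	KRAS	mutation	snv	negative	NA	G12D	1	NA	NA	Cobimetinib	D	TRUE
P17	KRAS	mutation	snv	G12C	1	G12C	1	NA	NA	AMG-510	B	TRUE
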