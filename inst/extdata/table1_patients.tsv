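# Cohort table: 17 lung adenocarcinoma patients with bone metastases.
# One row per patient; arms_pt / arms_bm are the rapid hotspot-PCR results
# per biopsy (NT = not tested, negative = tested negative); purities are
# histology tumor-cell fractions; initial_targeted is the targeted drug of
# the first-line regimen (none = chemo/radiotherapy only).
patient_id	age	sex	tnm_stage	histology_pt	histology_bm	arms_pt	arms_bm	purity_pt	purity_bm	treatment	initial_targeted	outcome_pt	outcome_bm	months
P1	50	F	cT3N2M1b IVa	AD	MAD	E19del	NT	0.55	0.51	Gefitinib + RT	Gefitinib	Progressive	Progressive	8
P2	70	M	cT4N0M1b IVa	AD	MAD	E19del	NT	0.31	0.20	Gefitinib + RT	Gefitinib	Stable	Stable	18
P3	54	M	cT1N2M1b IVa	AD	MAD	E19del	NT	0.50	0.45	Gefitinib + RT	Gefitinib	Stable	Progressive	10
P4	54	F	cT2N3M1b IVb	AD	MAD	E19del	NT	0.37	0.35	Gefitinib + RT	Gefitinib	Progressive	Progressive	14
P5	73	F	cT2N0M1c IVb	AD	MAD	E19del	NT	0.52	0.52	Gefitinib + RT	Gefitinib	Progressive	Stable	18
P6	67	M	cT2N2M1b IVa	AD	MAD	E19del	NT	0.26	0.32	Gefitinib + RT	Gefitinib	Stable	Stable	5
P7	64	F	cT2N2M1b IVa	P-NSCC	MAD	L858R	NT	0.24	0.37	Gefitinib	Gefitinib	Deceased	Deceased	7
P8	54	F	cT1N1M1b IVa	AD	MAD	L858R	NT	0.31	0.34	Gefitinib + CT + RT	Gefitinib	Progressive	Stable	3
P9	61	F	cT2N3M1c IVb	AD	MAD	L858R	NT	0.60	0.57	Erlotinib + CT	Erlotinib	Progressive	Stable	7
P10	50	M	cT1bN0M1c IVb	AD	MAD	negative	L858R	0.24	0.25	Osimertinib	Osimertinib	Stable	Stable	4
P11	66	M	cT1bN2M1c IVb	AD	MAD	negative	L858R	0.94	0.30	Gefitinib	Gefitinib	Progressive	Stable	17
P12	49	M	cT3N0M1c IVb	AD	MAD	G719X	NT	0.47	0.51	Osimertinib + RT	Osimertinib	Progressive	Stable	12
P13	59	M	cT3N0M1c IVb	AD	MAD	L861Q	NT	0.67	0.79	Gefitinib	Gefitinib	Deceased	Deceased	14
P14	52	M	cT1N2M1b IVa	AD	MAD	EML4-ALK	NT	0.70	0.33	Crizotinib + RT	Crizotinib	Stable	Stable	13
P15	63	M	cT2N2M1c IVb	AD	MAD	negative	NT	0.47	0.49	CT	none	Progressive	Progressive	5
P16	53	F	cT4N0M1a IVb	AD	MAD	negative	NT	0.35	0.35	CT + RT	none	Stable	Stable	3
P17	53	M	cT2N2M1b IVa	AD	MAD	negative	NT	0.33	0.74	CT + RT	none	Deceased	Deceased	2
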