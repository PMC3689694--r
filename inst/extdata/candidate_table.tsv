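gene_symbol	category	poly_rna	tot_rna	rr_printed	genbank
ACVR1B	Gene Expression	0.45	0.9	0.5	NM_004302
AKAP5	Gene Expression	1.3	0.8	1.7	NM_004857
ASH1L	Gene Expression	1.1	0.6	1.8	NM_018489
BRWD1	Gene Expression	1.7	0.8	2.2	NM_033656
CBX5	Gene Expression	0.9	2.0	0.5	NM_001127322
CRTC1	Gene Expression	0.9	1.4	0.6	NM_015321
DDX17	Gene Expression	0.6	1.9	0.3	NM_006386
HDAC8	Gene Expression	1.5	0.8	1.8	NM_018486
MLL5	Gene Expression	1.7	0.7	2.4	NM_182931
NFE2L3	Gene Expression	1.8	0.8	2.1	NM_004289
PHRF1	Gene Expression	0.5	1.2	0.4	NM_020901
POLR3G	Gene Expression	2.0	1.0	2.1	NM_006467
PRKACB	Gene Expression	0.5	1.4	0.4	NM_207578
THRA	Gene Expression	2.2	1.1	1.9	NM_199334
POLK	Genome Integrity and DNA Repair	2.2	0.9	2.3	NM_016218
REV1	Genome Integrity and DNA Repair	1.0	0.2	4.5	NM_016316
SMC5	Genome Integrity and DNA Repair	2.0	1.0	1.9	NM_015110
SMC6	Genome Integrity and DNA Repair	1.3	0.8	1.7	NM_001142286
TOP1	Genome Integrity and DNA Repair	1.3	0.7	1.9	NM_003286
BHLHE41	Cell Death and Survival	2.6	0.8	3.2	NM_030762
CD47	Cell Death and Survival	0.9	0.5	1.7	NM_001777
DNASE1L3	Cell Death and Survival	1.8	1.0	1.8	NM_004944
FOXO3	Cell Death and Survival	0.5	1.0	0.5	NM_001455
HIPK2	Cell Death and Survival	1.5	0.9	1.8	NM_022740
TRIB3	Cell Death and Survival	1.2	0.5	2.4	NM_021158
FAM110B	Cell Growth and Proliferation	0.4	0.8	0.5	NM_147189
PTK7	Cell Growth and Proliferation	2.1	0.6	3.6	NM_002821
RUNX1	Cell Growth and Proliferation	0.9	1.4	0.6	NM_001122607
TRAF4	Cell Growth and Proliferation	1.0	1.6	0.6	NM_004295
CDK6	Cell Cycle Control	0.9	0.3	2.7	NM_001259
CRY2	Cell Cycle Control	1.5	0.9	1.6	NM_021117
GSG2	Cell Cycle Control	1.0	1.6	0.6	NM_031965
NDE1	Cell Cycle Control	0.9	1.4	0.6	NM_001143979
RECQL	Cell Cycle Control	1.4	0.8	1.8	NM_002907
TPR	Cell Cycle Control	1.8	0.7	2.5	NM_003292
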