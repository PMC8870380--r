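patient_id	precursor_stage	gender	age_precursor_dx	age_mm_dx	ttp_months	n_serial_samples	precursor_detected	mm_detected	first_precursor_negative	passed_through_smm	genes
1	MGUS	F	72	73	6	2	nd	nd	FALSE	FALSE
2	SMM	F	85	86	12	2	X	X	FALSE	FALSE	ARID2,RASA2,IKBK,XBP1,KRAS
3	MGUS	F	80	81	15	3	X	X	FALSE	FALSE	FAM46C,BCL7A
4	MGUS	M	56	58	23	2	X	X	FALSE	FALSE	KRAS
5	MGUS	M	78	80	24	2	X	X	FALSE	FALSE	DNMT3A
6	SMM	M	74	76	25	2	X	X	FALSE	FALSE	KRAS
7	MGUS	F	67	70	39	2	nd	nd	FALSE	FALSE
8	MGUS	F	80	84	50	3	X	X	FALSE	FALSE	DIS3
9	MGUS	M	68	73	54	2	nd	nd	FALSE	FALSE
10	MGUS	M	65	71	68	3	X	X	TRUE	FALSE	NRAS
11	MGUS	F	56	62	72	2	X	X	FALSE	FALSE	TP53,HIST1HE
12	MGUS	M	67	73	78	6	X	X	FALSE	TRUE	PTPN11
13	MGUS	M	64	71	85	2	X	X	FALSE	FALSE	SP140,KRAS
14	MGUS	F	70	77	86	7	X	X	FALSE	TRUE	SETD2,FAM46C,KRAS
15	MGUS	F	54	61	87	6	X	X	TRUE	TRUE	NRAS
16	MGUS	M	62	70	91	4	X	X	FALSE	TRUE	PTPN11,MAX
17	MGUS	F	54	63	103	5	X	X	FALSE	FALSE	IDH1
18	MGUS	F	69	77	103	3	X	X	FALSE	TRUE	IRF4,HISTH1D
19	MGUS	M	50	59	105	2	nd	nd	FALSE	FALSE
20	MGUS	M	67	77	121	6	X	X	TRUE	TRUE	BRAF
21	MGUS	M	62	76	166	2	nd	X	FALSE	FALSE	BCL7A,KRAS
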