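# Cervical carcinoma cohort clinical follow-up (mean 63 months).
# status: alive at last follow-up; death = death from the primary cervical tumor;
# censored-death = died of unknown/other cause (censored in cause-specific analysis).
# analysis: CN = copy-number array only, EX = expression array only, CN/EX = both.
sample	histology	stage	age	treatment	followup_months	status	analysis
R035	SCC	IB2	48	TELE+CHEMO+HT	73	alive	CN/EX
R062	SCC	IB2	42	TELE+CHEMO+HT	62	alive	CN
R072	SCC	IB1	61	HT+TELE+BRACHY	86	alive	CN/EX
R075	ACC	IB1	73	TELE+HT	58	alive	CN/EX
R081	ACC	IB1	41	HT	62	alive	EX
R102	SCC	IIB	66	TELE+CHEMO+HT	84	alive	EX
R111	SCC	IB1	44	TELE+HT	78	alive	CN
R116	SCC	IB1	30	HT	26	death	CN
R121	SCC	IB1	35	HT	61	alive	EX
R124	SCC	IB1	42	HT	62	alive	EX
R154	SCC	IIIB	42	TELE+CHEMO	26	death	CN/EX
R156	SCC	IIIB	70	TELE+BRACHY+CHEMOi+HT	6	death	EX
R157	SCC	IVB	69	PALIATIVE CARE	2	death	EX
R158	SCC	IVB	37	PALIATIVE CARE	12	death	EX
R183	SCC	IB1	64	TELE+BRACHY	70	alive	CN/EX
R189	ACC	IB1	47	HT	60	alive	CN/EX
R194	SCC	IIA	64	UNTREATED	19	death	CN/EX
R198	SCC	IVA	50	PALIATIVE CARE	10	death	CN/EX
R208	SCC	IB1	46	TELE+BRACHY	23	death	CN/EX
R221	SCC	IB2	41	TELE+BRACHY+CHEMO	33	censored-death	CN/EX
R230	SCC	IB1	62	TELE+BRACHY	71	alive	EX
R240	SCC	IIIB	31	TELE+BRACHY+CHEMO	11	death	CN/EX
R244	SCC	IIB	52	TELE+HT	83	alive	CN/EX
R248	SCC	IB1	36	TELE+BRACHY+HT	24	death	CN
R260	SCC	IB2	24	TELE+CHEMO	66	alive	CN/EX
R265	SCC	IB1	46	TELE+BRACHY	67	alive	EX
R268	SCC	IIB	34	TELE+BRACHY+CHEMO	58	alive	EX
R282	SCC	IIIB	41	TELE+BRACHY+CHEMO	70	alive	CN/EX
R298	ASCC	IIIB	50	TELE+CHEMO+HT	48	death	CN/EX
R311	SCC	IIIB	72	UNTREATED	1	death	EX
R315	SCC	IIIB	41	TELE+BRACHY+CHEMO	10	death	EX
R322	SCC	IIIB	74	TELE+BRACHY	60	alive	CN/EX
R324	SCC	IB2	28	TELE+BRACHY+CHEMO	14	death	EX
R330	SCC	IB1	72	TELE+BRACHY	54	alive	EX
R336	SCC	IB2	36	TELE+BRACHY+CHEMO	64	alive	EX
R339	SCC	IB2	31	TELE+BRACHY+CHEMO	13	death	EX
R365	SCC	IIIB	38	TELE+CHEMO	6	death	CN/EX
R368	SCC	IIIB	36	TELE+BRACHY+CHEMOi	70	alive	EX
R369	SCC	IB1	50	HT	65	alive	CN/EX
R378	SCC	IB2	42	TELE+BRACHY+CHEMO	56	alive	EX
R380	SCC	IIIB	64	UNTREATED	12	death	CN/EX
R386	SCC	IB1	73	TELE+BRACHY	70	alive	CN/EX
R390	SCC	IB1	51	TELE+BRACHY+CHEMOi	64	alive	EX
R392	SCC	IIIB	69	TELE+BRACHY	61	alive	CN/EX
R409	SCC	IB2	68	TELE+BRACHY+CHEMO	42	alive	EX
R411	SCC	IB1	34	HT+TELE+BRACHY	60	alive	EX
R412	SCC	IB2	33	TELE+BRACHY+CHEMO	63	alive	EX
R426	SCC	IIB	67	TELE+BRACHY+CHEMO	23	death	EX
R444	SCC	IIB	71	UNTREATED	26	death	CN/EX
R455	SCC	IIA	67	TELE+BRACHY	60	alive	EX
R457	SCC	IIIB	60	TELE+BRACHY	15	death	EX
R476	SCC	IB1	41	HT	68	alive	CN/EX
R478	SCC	IB1	46	TELE+BRACHY	60	alive	CN/EX
R483	SCC	IVB	51	PALIATIVE CARE	11	death	CN/EX
R486	SCC	IB1	39	TELE+HT	33	alive	EX
R489	SCC	IIIB	43	TELE+BRACHY	37	alive	EX
R494	SCC	IIIB	55	TELE+CHEMO+BRACHYi	6	death	CN/EX
R495	SCC	IIB	68	TELE+BRACHY	62	alive	EX
R496	SCC	IIIB	52	TELE+BRACHY+CHEMO	63	alive	CN/EX
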