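donor	group	image	marker	positive	total
AD01	AD	1	ERBB4	39	120
AD02	AD	1	ERBB4	32	120
AD03	AD	1	ERBB4	39	120
AD04	AD	1	ERBB4	34	120
AD05	AD	1	ERBB4	37	120
AD06	AD	1	ERBB4	24	120
AD07	AD	1	ERBB4	39	120
AD08	AD	1	ERBB4	27	120
AD09	AD	1	ERBB4	32	120
AD10	AD	1	ERBB4	30	120
C01	control	1	ERBB4	52	120
C02	control	1	ERBB4	47	120
C03	control	1	ERBB4	59	120
C04	control	1	ERBB4	54	120
C05	control	1	ERBB4	47	120
C06	control	1	ERBB4	48	120
C07	control	1	ERBB4	47	120
C08	control	1	ERBB4	51	120
C09	control	1	ERBB4	42	120
C10	control	1	ERBB4	46	120
AD01	AD	1	NFIA	19	120
AD02	AD	1	NFIA	19	120
AD03	AD	1	NFIA	20	120
AD04	AD	1	NFIA	15	120
AD05	AD	1	NFIA	21	120
AD06	AD	1	NFIA	15	120
AD07	AD	1	NFIA	22	120
AD08	AD	1	NFIA	23	120
AD09	AD	1	NFIA	21	120
AD10	AD	1	NFIA	22	120
C01	control	1	NFIA	41	120
C02	control	1	NFIA	52	120
C03	control	1	NFIA	44	120
C04	control	1	NFIA	40	120
C05	control	1	NFIA	40	120
C06	control	1	NFIA	44	120
C07	control	1	NFIA	47	120
C08	control	1	NFIA	56	120
C09	control	1	NFIA	37	120
C10	control	1	NFIA	39	120
AD01	AD	1	SOX9	41	120
AD02	AD	1	SOX9	38	120
AD03	AD	1	SOX9	37	120
AD04	AD	1	SOX9	34	120
AD05	AD	1	SOX9	39	120
AD06	AD	1	SOX9	38	120
AD07	AD	1	SOX9	38	120
AD08	AD	1	SOX9	37	120
AD09	AD	1	SOX9	35	120
AD10	AD	1	SOX9	38	120
C01	control	1	SOX9	39	120
C02	control	1	SOX9	36	120
C03	control	1	SOX9	33	120
C04	control	1	SOX9	44	120
C05	control	1	SOX9	37	120
C06	control	1	SOX9	32	120
C07	control	1	SOX9	28	120
C08	control	1	SOX9	33	120
C09	control	1	SOX9	32	120
C10	control	1	SOX9	42	120
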