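gene	selected	eoo_all	vlf_all	ctrl_all	eoo_path	vlf_path	ctrl_path
ADRB3	FALSE	1	1	4	0	0	1
BDNF	TRUE	4	1	0	3	1	0
FTO	TRUE	4	4	1	1	0	0
GHSR	FALSE	2	6	3	0	1	0
LEP	FALSE	0	0	0	0	0	0
LEPR	FALSE	7	5	5	2	2	3
MC3R	TRUE	3	3	0	2	1	0
MC4R	TRUE	7	6	2	6	4	0
NEGR1	TRUE	3	0	0	1	0	0
NTRK2	FALSE	2	3	4	1	2	1
PCSK1	FALSE	4	0	5	3	0	1
PCSK2	FALSE	2	0	5	0	0	2
PPARG	TRUE	3	0	0	2	0	0
SIM1	TRUE	6	2	1	2	0	0
TMEM18	FALSE	0	1	1	0	1	0
TOTAL	NA	48	32	31	23	12	8
SELECTED	NA	30	16	4	17	6	0
OTHER	NA	18	16	27	6	6	8
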