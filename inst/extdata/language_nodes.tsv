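node	seed	cluster_size	ba	peak_t	x	y	z
IFGtriang.L	Broca	1252	48	39.27	-51	21	15
TPOsup.R	Broca	128	38	14.61	48	21	18
IFGtriang.R	Broca	80	14	11.53	57	30	9
MTG.L	Broca	307	22	11.20	-60	-42	6
MTG.R	Broca	153	21	10.43	69	-36	-3
SFGmed.L	Broca	99	9	10.07	0	45	39
ANG.R	Broca	51	NA	8.93	39	-66	36
SMG.L	Wernicke	786	40	37.17	-54	-51	30
SMG.R	Wernicke	391	48	13.19	51	-42	30
MFG.L	Wernicke	157	9	12.58	-42	12	45
ORBinf.R	Wernicke	58	NA	12.15	51	33	-15
Cerebellum.R	Wernicke	170	NA	11.48	33	-69	-42
ORBinf.L	Wernicke	191	47	10.58	-39	42	-15
IFGoperc.R	Wernicke	59	44	10.43	57	18	12
MFG.R	Wernicke	115	46	10.31	42	36	33
CUN.L	Wernicke	50	NA	9.91	-9	-75	36
Cerebellum.L	Wernicke	128	NA	9.55	-18	-78	-39
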