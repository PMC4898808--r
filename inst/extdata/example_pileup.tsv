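gene001	1	A	55	0	0	0	0
gene001	2	T	0	0	0	81	0
gene001	3	G	0	0	53	0	0
gene001	4	A	80	0	0	0	0
gene001	5	T	0	0	0	52	0
gene001	6	A	33	0	0	0	0
gene001	7	G	0	0	55	0	0
gene001	8	C	1	94	0	0	0
gene001	9	A	40	0	0	0	0
gene001	10	G	0	0	28	0	0
gene001	11	A	50	0	0	0	0
gene001	12	C	0	29	0	0	0
gene001	13	A	51	0	0	0	0
gene001	14	C	0	92	0	0	0
gene001	15	T	0	0	0	70	0
gene001	16	C	0	103	0	0	0
gene001	17	T	0	0	0	73	0
gene001	18	C	0	46	0	0	0
gene001	19	T	0	0	0	99	0
gene001	20	G	0	0	34	0	0
gene001	21	C	0	49	0	19	0
gene001	22	G	0	0	85	0	0
gene001	23	A	39	0	0	0	0
gene001	24	C	0	103	0	0	0
gene001	25	A	64	0	0	0	0
gene001	26	G	0	0	104	0	0
gene001	27	T	0	0	0	109	0
gene001	28	A	45	0	0	0	0
gene001	29	A	49	0	0	0	0
gene001	30	C	0	70	0	0	0
gene001	31	T	0	0	0	35	0
gene001	32	T	0	0	0	23	0
gene001	33	T	0	0	0	87	0
gene001	34	C	0	45	0	0	0
gene001	35	G	0	0	54	0	0
gene001	36	G	0	0	62	0	0
gene001	37	G	0	1	44	0	0
gene001	38	C	0	73	0	0	0
gene001	39	T	0	0	0	49	0
gene001	40	T	0	0	0	41	0
gene001	41	T	0	0	0	52	0
gene001	42	A	50	0	0	0	0
gene001	43	A	94	0	0	0	0
gene001	44	C	0	82	0	0	0
gene001	45	C	0	50	54	0	0
gene001	46	T	0	0	0	115	0
gene001	47	C	0	31	0	0	0
gene001	48	C	1	67	0	0	0
gene001	49	C	0	57	0	0	0
gene001	50	A	66	0	0	0	0
gene001	51	T	0	0	0	75	0
gene001	52	G	1	0	93	0	0
gene001	53	C	0	13	0	0	0
gene001	54	A	55	0	0	0	0
gene001	55	T	0	0	0	27	0
gene001	56	G	0	0	66	0	0
gene001	57	T	0	0	0	92	0
gene001	58	A	62	0	0	0	0
gene001	59	A	52	0	0	0	0
gene001	60	A	58	0	0	0	0
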