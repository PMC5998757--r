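direct_no	start	target	node2vec	cooccurrence	deepwalk
1	INS	INSR	10	-	-
2	INSR	IRS1/IRS	4	1	7
3	IRS1/IRS	PI3K	1	3	1
4	INSR	SOCS	8	10	6
5	SOCS	IRS1/IRS	2	3	2
6	IKK	IRS1/IRS	2	2	2
7	JNK	IRS1/IRS	4	5	4
8	PKCZ	IRS1/IRS	6	-	7
9	PKCD/E	IRS1/IRS	2	4	2
10	ADIPO	ADIPOR	1	1	1
11	AMPKK	AMPK	1	1	1
12	INSR	SHC	38	-	67
13	SHC	GRB2	5	5	16
14	GRB2	SOS	-	-	-
15	SOS	Ras	-	-	-
16	Ras	Raf	4	6	-
17	Raf	MEK1/2	1	5	4
18	MEK1/2	ERK1/2	1	1	1
19	IRS1/IRS	GRB2	4	4	4
20	PI3K	PDK1/2	1	2	6
21	PDK1/2	AKT	3	4	5
22	AKT	GLUT4	4	4	4
23	PDK1/2	PKCZ	1	1	1
24	PKCZ	GLUT4	3	2	3
25	AKT	mTOR	1	1	1
26	TNFA	TNFR1	6	1	6
27	TNFA	TNFR2	4	1	6
28	TNFR1	TRADD	-	-	-
29	TRADD	TNFR2	-	-	-
30	TNFR2	TRAF2	-	-	-
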