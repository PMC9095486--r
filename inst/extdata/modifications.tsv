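code	name	family	C	H	N	O	P	S	source
A	adenosine	A	10	13	5	4	0	0	canonical
G	guanosine	G	10	13	5	5	0	0	canonical
C	cytidine	C	9	13	3	5	0	0	canonical
U	uridine	U	9	12	2	6	0	0	canonical
Y	pseudouridine	U	9	12	2	6	0	0	canonical
D	dihydrouridine	U	9	14	2	6	0	0	modomics
s4U	4-thiouridine	U	9	12	2	5	0	1	modomics
m5C	5-methylcytidine	C	10	15	3	5	0	0	modomics
m5U	5-methyluridine	U	10	14	2	6	0	0	modomics
m5s2U	5-methyl-2-thiouridine	U	10	14	2	5	0	1	modomics
m1A	1-methyladenosine	A	11	15	5	4	0	0	modomics
m2G	N2-methylguanosine	G	11	15	5	5	0	0	modomics
m22G	N2,N2-dimethylguanosine	G	12	17	5	5	0	0	modomics
m7G	7-methylguanosine	G	11	15	5	5	0	0	modomics
ac4C	N4-acetylcytidine	C	11	15	3	6	0	0	modomics
G+	archaeosine	G	12	16	6	5	0	0	modomics
acp3U	3-(3-amino-3-carboxypropyl)uridine	U	13	19	3	8	0	0	modomics
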