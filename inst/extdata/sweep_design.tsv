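# sixteen-case sweep design: corneal constants (C10 MPa, k1 MPa, k2 -),
# intraocular pressure (mmHg) and central corneal thickness (um)
simulation	C10	k1	k2	IOP	CCT
1	0.045	0.027	180	10	558
2	0.045	0.027	180	15	558
3	0.045	0.027	180	20	558
4	0.045	0.027	180	25	558
5	0.045	0.027	180	30	558
6	0.0675	0.027	180	15	558
7	0.0225	0.027	180	15	558
8	0.045	0.0405	180	15	558
9	0.045	0.0135	180	15	558
10	0.045	0.027	270	15	558
11	0.045	0.027	90	15	558
12	0.035	0.13	1000	15	558
13	0.01	0.015	100	15	558
14	0.045	0.027	180	15	484
15	0.045	0.027	180	15	525
16	0.045	0.027	180	15	600
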