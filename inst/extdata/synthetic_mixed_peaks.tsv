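position	strand	A	C	G	T
1	F	1	0.02	0.02	0.02
1	R	1	0.02	0.02	0.02
2	F	1	0.02	0.02	0.02
2	R	1	0.02	0.02	0.02
3	F	0.02	1	0.02	0.02
3	R	0.02	1	0.02	0.02
4	F	0.02	0.02	1	0.02
4	R	0.02	0.02	1	0.02
5	F	0.02	0.02	1	0.02
5	R	0.02	0.02	1	0.02
6	F	1	0.02	0.02	0.02
6	R	1	0.02	0.02	0.02
7	F	0.02	1	0.02	0.02
7	R	0.02	1	0.02	0.02
8	F	0.4	0.02	0.6	0.02
8	R	0.02	0.02	1	0.02
9	F	1	0.02	0.02	0.02
9	R	1	0.02	0.02	0.02
10	F	0.02	0.02	0.02	1
10	R	0.02	0.02	0.02	1
11	F	0.02	0.02	1	0.02
11	R	0.02	0.02	1	0.02
12	F	0.02	0.65	0.02	0.35
12	R	0.02	0.65	0.02	0.35
13	F	0.02	0.02	1	0.02
13	R	0.02	0.02	1	0.02
14	F	0.02	0.02	0.02	1
14	R	0.02	0.02	0.02	1
15	F	0.02	0.02	1	0.02
15	R	0.02	0.02	1	0.02
16	F	0.02	0.02	0.02	1
16	R	0.02	0.02	0.02	1
17	F	1	0.02	0.02	0.02
17	R	1	0.02	0.02	0.02
18	F	0.02	0.02	0.02	1
18	R	0.02	0.02	0.02	1
19	F	0.02	0.02	1	0.02
19	R	0.02	0.02	1	0.02
20	F	0.02	0.02	1	0.02
20	R	0.02	0.02	1	0.02
21	F	0.02	1	0.02	0.02
21	R	0.02	1	0.02	0.02
22	F	0.02	0.02	0.02	1
22	R	0.02	0.02	0.02	1
23	F	0.02	0.02	1	0.02
23	R	0.02	0.02	1	0.02
24	F	0.02	0.02	0.02	1
24	R	0.02	0.02	0.02	1
25	F	0.02	0.35	0.02	0.65
25	R	0.02	0.35	0.02	0.65
26	F	1	0.02	0.02	0.02
26	R	1	0.02	0.02	0.02
27	F	0.02	0.02	1	0.02
27	R	0.02	0.02	1	0.02
28	F	1	0.02	0.02	0.02
28	R	1	0.02	0.02	0.02
29	F	0.02	1	0.02	0.02
29	R	0.02	1	0.02	0.02
30	F	0.02	0.02	0.02	1
30	R	0.02	0.02	0.02	1
31	F	1	0.02	0.02	0.02
31	R	1	0.02	0.02	0.02
32	F	1	0.02	0.02	0.02
32	R	1	0.02	0.02	0.02
33	F	0.02	0.35	0.02	0.65
33	R	0.02	0.35	0.02	0.65
34	F	0.02	1	0.02	0.02
34	R	0.02	1	0.02	0.02
35	F	0.02	0.02	0.02	1
35	R	0.02	0.02	0.02	1
36	F	0.02	1	0.02	0.02
36	R	0.02	1	0.02	0.02
37	F	0.02	0.02	0.02	1
37	R	0.02	0.02	0.02	1
38	F	1	0.02	0.02	0.02
38	R	1	0.02	0.02	0.02
39	F	0.02	1	0.02	0.02
39	R	0.02	1	0.02	0.02
40	F	0.02	0.02	0.02	1
40	R	0.02	0.02	0.02	1
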