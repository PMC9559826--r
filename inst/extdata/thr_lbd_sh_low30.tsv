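# Reference function-specific score list for the THR-like LBD family:
# the 30 residues with the lowest combined Sequence Harmony (SH) scores
# (selection cutoff SH < 0.4), numbered on the thyroid hormone receptor
# alpha structure (PDB 1NAV chain A).
rank	score	residue	residue_number
1	0.20538	C	392
2	0.240834	S	271
3	0.258853	K	220
4	0.26986	P	224
5	0.29622	L	292
6	0.300094	S	277
7	0.301198	A	281
8	0.30187	S	216
9	0.307977	M	280
10	0.309991	G	207
11	0.313866	A	263
12	0.314308	E	213
13	0.316865	R	228
14	0.330136	C	244
15	0.332867	S	240
16	0.333702	C	380
17	0.334945	M	259
18	0.336439	H	355
19	0.341662	I	222
20	0.350112	E	217
21	0.351103	V	265
22	0.354989	R	384
23	0.359096	C	255
24	0.360052	L	386
25	0.36292	S	296
26	0.366648	D	272
27	0.366816	Q	286
28	0.369598	L	396
29	0.371785	F	401
30	0.372781	D	211
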