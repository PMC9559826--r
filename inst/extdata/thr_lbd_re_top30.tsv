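# Reference fold-specific score list for the THR-like LBD family:
# the 30 residues with the highest relative-entropy (RE) scores,
# numbered on the thyroid hormone receptor alpha structure
# (PDB 1NAV chain A).
rank	score	residue	residue_number
1	2.86093	F	239
2	2.736545	F	232
3	2.735418	Q	247
4	2.610201	D	246
5	2.39529	K	234
6	2.372856	R	375
7	2.334283	L	302
8	2.314478	K	252
9	2.293988	Q	342
10	2.222085	H	381
11	2.191814	R	329
12	2.183281	E	257
13	2.148886	P	237
14	2.095029	D	328
15	2.073641	L	250
16	2.023249	E	315
17	1.922814	A	321
18	1.875692	L	318
19	1.870668	L	242
20	1.77909	F	300
21	1.773385	K	357
22	1.748892	L	251
23	1.747452	F	349
24	1.702621	P	399
25	1.7008	Y	267
26	1.687514	L	374
27	1.672857	E	403
28	1.657511	I	338
29	1.648088	F	215
30	1.634578	F	309
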