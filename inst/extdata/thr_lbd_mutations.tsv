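# Disease-associated natural mutations in THR-like receptor
# ligand-binding domains, compiled from UniProtKB variant annotation.
# reported_classification: curated fold/function label;
# alignment_position: position in the family consensus alignment.
receptor	mutation	reported_classification	alignment_position	disease
THRA	N359Y	Function	484	CHNG6; atypical phenotype; weak reduction in transcriptional activation
THRA	A263S	Function	258	CHNG6; no effect on T3 binding
THRB	R429Q/W	Fold	506	PRTH
THRB	S350L	Function	368	GRTHD
THRB	V349M	Fold	367	GRTHD
THRB	V348E	Function	366	GRTHD
THRB	G347E/A	Fold	364	GRTHD
THRB	L346F	Fold/Function	363	GRTHD
THRB	G345R/V/S	Fold	361	GRTHD
THRB	G344E/A	Function	360	GRTHD
THRB	K342I	Function	343	GRTHD
THRB	L341P	Function	336	GRTHD
THRB	Q340H	Function	335	GRTHD
THRB	R338W/L	Fold	295	GRTHD
THRB	Del337T	Function	294	GRTHD
THRB	A335P	Function	292	GRTHD
THRB	E333D	Fold	277	GRTHD
THRB	G332R/E	Function	276	GRTHD
THRB	N331D	Function	275	GRTHD
THRB	L330S	Fold	273	GRTHD
THRB	T329I	Function	272	GRTHD
THRB	T327A	Function	269	GRTHD
THRB	Y321C/H	Fold	262	GRTHD
THRB	R320H/G	Function	261	GRTHD
THRB	A317T/S	Function	258	GRTHD; impairs hormone binding
THRB	R316H/C	Fold	257	PRTH; impairs hormone binding
THRB	A268G	Function	207	GRTHD
THRB	R243W	Fold	80	GRTHD
THRB	A234T	Function	71	GRTHD; impairs hormone binding and ligand-dependent conformational changes
RARB	R394C	Function	523	MCOPS12; increased transcriptional response to retinoic acid ligands
RARB	R394S	Function	523	MCOPS12; increases transcriptional response to retinoic acid
RARB	G303A	Fold	361	MCOPS12; increased transcriptional response to retinoic acid ligands
RARB	L220P	Function	204	MCOPS12; increased transcriptional response to retinoic acid ligands
VDR	R391C	Fold	506	VDDR2A
VDR	S360P	Function	456	VDDR2A; loss of calcitriol receptor activity
VDR	V346M	Fold	422	VDDR2A; decreased calcitriol receptor activity
VDR	I314S	Fold	372	VDDR2A
VDR	H305Q	Fold/Function	363	VDDR2A; loss of calcitriol receptor activity
VDR	R274L/H	Fold	257	VDDR2A; decreased affinity for calcitriol
PPARG	P495L	Fold	542	Diabetes
PPARG	R425C	Fold	418	FPLD3
PPARG	F388L	Fold/Function	363	FPLD3
PPARG	V318M	Fold	216	Diabetes
PPARG	R316H	Function	214	Colon cancer; somatic; partial loss of ligand-binding
PPARG	Q314P	Function	212	Colon cancer; somatic; loss of ligand-binding
RORA	R462Q	Function	481	IDDECA; loss of function in cerebellar development
RORA	S409R	Function	379	IDDECA
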