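# Conserved motifs of the THR-like LBD consensus alignment
# (1-based inclusive alignment-column ranges).
# Interaction sites INS1-INS5 have no published coordinates and are
# intentionally absent; supply them via a user motif table if known.
name	start	end	category
Motif A	207	216	motif
Motif B	222	232	motif
Motif C	236	245	motif
Motif D	396	401	motif
Motif E	455	459	motif
Motif F	498	504	motif
Motif G	540	548	motif
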