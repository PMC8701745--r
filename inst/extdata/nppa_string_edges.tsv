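protein_a	protein_b	channel	score
NPPA	NPR3	physical	0.89
NPPA	ATP2A2	textmining	0.58
NPPA	ADM	textmining	0.55
NPPA	TBX18	textmining	0.48
NPPA	PITX2	textmining	0.46
NPPA	POSTN	textmining	0.41
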