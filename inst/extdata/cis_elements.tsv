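element	pattern	note
ABRE	ACGTG	ABA-responsive element core (ACGT-containing G-box core, PLACE-style)
DRE	RCCGAC	dehydration-responsive element / C-repeat core, R = A or G (PLACE-style)
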