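19	27365474	27369000	GENEA	0	+
19	27499999	27550000	GENEB	0	-
19	31249999	31260000	GENEC	0	+
5	26899999	26949409	GENED	0	+
5	39999999	40010000	GENEE	0	.
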