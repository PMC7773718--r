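primer_pair	asv	taxon	JM1	JM2	JM3	JM4	identity_pct
647F-847R	ASV1	Senna occidentalis	56065	564176	11901	400029	100
647F-847R	ASV2	Senna obtusifolia	57978	31078	321102	348064	100
478F-629R	ASV3	Senna occidentalis	108018	288609	6666	65827	100
478F-629R	ASV4	Senna obtusifolia	27160	2937	79349	3718	100
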