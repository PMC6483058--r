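# SYNTHETIC fixture: directed PPI overlay for the AD-scale pathway
# 112 in-universe edges + 3 out-of-universe decoys
FLR02	NEW01	1
NEW01	NEW02	1
NEW02	NEW03	1
NEW03	NEW04	1
NEW04	NEW05	1
NEW05	NEW06	1
NEW06	NEW07	1
NEW07	NEW08	1
NEW08	NEW09	1
NEW09	NEW10	1
NEW10	NEW11	1
NEW11	NEW12	1
NEW12	NEW13	1
NEW13	NEW14	1
NEW14	NEW15	1
NEW15	NEW16	1
NEW16	NEW17	1
NEW17	NEW18	1
NEW18	NEW19	1
NEW19	NEW20	1
NEW20	NEW21	1
NEW21	NEW22	1
NEW22	NEW23	1
NEW23	NEW24	1
NEW24	NEW25	1
NEW25	NEW26	1
NEW26	NEW27	1
NEW27	NEW28	1
NEW28	NEW29	1
NEW29	NEW30	1
NEW30	NEW31	1
NEW31	NEW32	1
NEW32	NEW33	1
NEW33	NEW34	1
FLR01	FLR03	1
FLR01	FLR04	1
FLR01	FLR05	1
FLR01	FLR06	1
FLR01	FLR07	1
FLR01	FLR08	1
FLR01	FLR09	1
FLR01	FLR10	1
FLR01	FLR11	1
FLR01	FLR12	1
FLR01	FLR13	1
FLR01	FLR14	1
FLR01	FLR15	1
FLR01	FLR16	1
FLR01	FLR17	1
FLR01	FLR18	1
FLR01	FLR19	1
FLR01	FLR20	1
FLR01	FLR21	1
FLR01	FLR22	1
FLR01	FLR23	1
FLR01	FLR24	1
FLR02	FLR01	1
FLR02	FLR03	1
FLR02	FLR04	1
FLR02	FLR05	1
FLR02	FLR06	1
FLR02	FLR07	1
FLR02	FLR08	1
FLR02	FLR09	1
FLR02	FLR10	1
FLR02	FLR11	1
FLR02	FLR12	1
FLR02	FLR13	1
FLR02	FLR14	1
FLR02	FLR15	1
FLR02	FLR16	1
FLR02	FLR17	1
FLR02	FLR18	1
FLR02	FLR19	1
FLR02	FLR20	1
FLR02	FLR21	1
FLR02	FLR22	1
FLR02	FLR23	1
FLR02	FLR24	1
FLR03	FLR01	1
FLR03	FLR02	1
FLR03	FLR05	1
FLR03	FLR06	1
FLR03	FLR07	1
FLR03	FLR08	1
FLR03	FLR09	1
FLR03	FLR10	1
FLR03	FLR11	1
FLR03	FLR12	1
FLR03	FLR13	1
FLR03	FLR14	1
FLR03	FLR15	1
FLR03	FLR16	1
FLR03	FLR17	1
FLR03	FLR18	1
FLR03	FLR19	1
FLR03	FLR20	1
FLR03	FLR21	1
FLR03	FLR22	1
FLR03	FLR23	1
FLR03	FLR24	1
FLR04	FLR01	1
FLR04	FLR02	1
FLR04	FLR03	1
FLR04	FLR05	1
FLR04	FLR06	1
FLR04	FLR07	1
FLR04	FLR08	1
FLR04	FLR09	1
FLR04	FLR10	1
FLR04	FLR11	1
FLR04	FLR12	1
XOFF1	XOFF2	1
XOFF3	XOFF4	1
XOFF5	XOFF6	1
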