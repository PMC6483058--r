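# SYNTHETIC fixture: 171-gene universe of the AD-scale pathway
APAF1
APBB1
APP
CAPN1
CASP3
CASP8
FLR01
FLR02
FLR03
FLR04
FLR05
FLR06
FLR07
FLR08
FLR09
FLR10
FLR11
FLR12
FLR13
FLR14
FLR15
FLR16
FLR17
FLR18
FLR19
FLR20
FLR21
FLR22
FLR23
FLR24
MAPT
NEW01
NEW02
NEW03
NEW04
NEW05
NEW06
NEW07
NEW08
NEW09
NEW10
NEW11
NEW12
NEW13
NEW14
NEW15
NEW16
NEW17
NEW18
NEW19
NEW20
NEW21
NEW22
NEW23
NEW24
NEW25
NEW26
NEW27
NEW28
NEW29
NEW30
NEW31
NEW32
NEW33
NEW34
PAD001
PAD002
PAD003
PAD004
PAD005
PAD006
PAD007
PAD008
PAD009
PAD010
PAD011
PAD012
PAD013
PAD014
PAD015
PAD016
PAD017
PAD018
PAD019
PAD020
PAD021
PAD022
PAD023
PAD024
PAD025
PAD026
PAD027
PAD028
PAD029
PAD030
PAD031
PAD032
PAD033
PAD034
PAD035
PAD036
PAD037
PAD038
PAD039
PAD040
PAD041
PAD042
PAD043
PAD044
PAD045
PAD046
PAD047
PAD048
PAD049
PAD050
PAD051
PAD052
PAD053
PAD054
PAD055
PAD056
PAD057
PAD058
PAD059
PAD060
PAD061
PAD062
PAD063
PAD064
PAD065
PAD066
PAD067
PAD068
PAD069
PAD070
PAD071
PAD072
PAD073
PAD074
PAD075
PAD076
PAD077
PAD078
PAD079
PAD080
PAD081
PAD082
PAD083
PAD084
PAD085
PAD086
PAD087
PAD088
PAD089
PAD090
PAD091
PAD092
PAD093
PAD094
PAD095
PAD096
PAD097
PAD098
PAD099
PAD100
PAD101
PAD102
PAD103
PSEN1
PSEN2
SNCA
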