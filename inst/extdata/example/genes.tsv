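g001
g002
g003
g004
g005
g006
g007
g008
g009
g010
g011
g012
g013
g014
g015
g016
g017
g018
g019
g020
g021
g022
g023
g024
g025
g026
g027
g028
g029
g030
g031
g032
g033
g034
g035
g036
g037
g038
g039
g040
g041
g042
g043
g044
g045
g046
g047
g048
g049
g050
g051
g052
g053
g054
g055
g056
g057
g058
g059
g060
g061
g062
g063
g064
g065
g066
g067
g068
g069
g070
g071
g072
g073
g074
g075
g076
g077
g078
g079
g080
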