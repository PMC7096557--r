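n00001
n00002
n00003
n00004
n00005
n00006
n00007
n00008
n00009
n00010
n00011
n00012
n00013
n00014
n00015
n00016
n00017
n00018
n00019
n00020
n00021
n00022
n00023
n00024
n00025
n00026
n00027
n00028
n00029
n00030
n00031
n00032
n00033
n00034
n00035
n00036
n00037
n00038
n00039
n00040
n00041
n00042
n00043
n00044
n00045
n00046
n00047
n00048
n00049
n00050
n00051
n00052
n00053
n00054
n00055
n00056
n00057
n00058
n00059
n00060
n00061
n00062
n00063
n00064
n00065
n00066
n00067
n00068
n00069
n00070
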