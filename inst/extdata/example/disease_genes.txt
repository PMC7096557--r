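g031
g032
g033
g034
g035
g036
g037
g038
g039
g040
g071
g072
g073
g074
g075
g076
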