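series,region,n_points
HN,head and neck,15
CA,chest and abdomen,1
B,back,9
UE,upper extremity,11
LE,lower extremity,12
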