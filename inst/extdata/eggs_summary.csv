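source,n,vitd3_mean,vitd3_sd,ohd3_mean,ohd3_sd
cage,14,1.31,0.45,0.38,0.09
free_range,12,1.45,0.45,0.48,0.10
indoor_free_range,4,1.08,0.21,0.46,0.12
organic,4,1.35,0.49,0.42,0.15
all_types,34,1.34,0.43,0.43,0.11
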