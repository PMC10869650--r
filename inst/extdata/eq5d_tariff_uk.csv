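dimension,level,decrement
any_dysfunction,,0.081
worst_level,,0.269
mobility,2,0.069
mobility,3,0.314
selfcare,2,0.104
selfcare,3,0.214
activity,2,0.036
activity,3,0.094
pain,2,0.123
pain,3,0.386
anxiety,2,0.071
anxiety,3,0.236
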