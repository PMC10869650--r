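dimension,level,decrement
any_dysfunction,,0.004
worst_level,,0.020
item1,2,0.004
item1,3,0.010
item1,4,0.020
item2,2,0.004
item2,3,0.010
item2,4,0.020
item3,2,0.004
item3,3,0.010
item3,4,0.020
item4,2,0.004
item4,3,0.010
item4,4,0.020
item5,2,0.004
item5,3,0.010
item5,4,0.020
item6,2,0.004
item6,3,0.010
item6,4,0.020
item7,2,0.004
item7,3,0.010
item7,4,0.020
item8,2,0.004
item8,3,0.010
item8,4,0.020
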