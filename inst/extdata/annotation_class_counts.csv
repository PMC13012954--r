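dataset,class,count
hl60,negative,818
hl60,spread,735
hl60,disintegrated,763
hl60,netosis,607
hl60,dead,1963
mouse,negative,441
mouse,spread,496
mouse,disintegrated,364
mouse,netosis,247
mouse,dead,635
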