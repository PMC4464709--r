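patient,cine_ml,reference_ml
1,62.5,59.0
2,61.5,71.0
3,395.0,397.0
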