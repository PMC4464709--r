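shape,volume_ml,reference_ml
oval_big,54.9,54.0
oval_small,48.9,51.0
oval_oblique,58.4,61.0
spherical,53.5,55.0
curved,68.4,70.0
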