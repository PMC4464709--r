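shape,strategy,method,volume_ml,reference_ml
oval_big,A1,nonmodel,51.0,54.0
oval_big,A2,nonmodel,50.9,54.0
oval_big,A3,nonmodel,52.8,54.0
oval_small,B1,nonmodel,45.7,51.0
oval_small,B2,nonmodel,46.4,51.0
oval_small,B3,nonmodel,46.5,51.0
oval_oblique,C1,nonmodel,55.3,61.0
oval_oblique,C2,nonmodel,55.3,61.0
oval_oblique,C3,nonmodel,54.4,61.0
spherical,D1,nonmodel,48.2,55.0
spherical,D2,nonmodel,47.2,55.0
spherical,D3,nonmodel,49.8,55.0
curved,E1,nonmodel,65.8,70.0
curved,E2,nonmodel,67.5,70.0
curved,E3,nonmodel,65.3,70.0
oval_big,A1,arealength,52.67,54.0
oval_big,A2,arealength,50.29,54.0
oval_big,A3,arealength,46.51,54.0
oval_small,B1,arealength,48.38,51.0
oval_small,B2,arealength,47.76,51.0
oval_small,B3,arealength,45.03,51.0
oval_oblique,C1,arealength,55.92,61.0
oval_oblique,C2,arealength,57.28,61.0
oval_oblique,C3,arealength,42.57,61.0
spherical,D1,arealength,50.10,55.0
spherical,D2,arealength,51.66,55.0
spherical,D3,arealength,49.96,55.0
curved,E1,arealength,61.02,70.0
curved,E2,arealength,63.23,70.0
curved,E3,arealength,54.29,70.0
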