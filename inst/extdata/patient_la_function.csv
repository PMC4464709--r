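patient,v_max,v_min,v_pre_a,lv_sv,total_conduit,total_ef,passive_emptying,active_emptying,passive_fraction,active_fraction,passive_la_flow
1,82.6,43.6,64.4,104,39.0,47.2,18.2,20.8,47,53,65
2,70.6,40.6,61.9,73.7,30.0,42.5,8.7,21.3,29,71,43.7
3,418,376,NA,66.4,42,10.0,42,0,100,0,24.4
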