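parameter,treatment,units,observed,reference_model
dmi,maize_lablab,kg/animal/day,9.8,14.4
dmi,oats_vetch,kg/animal/day,9.7,14.2
final_bw,maize_lablab,kg/animal,386,454
final_bw,oats_vetch,kg/animal,399,430
milk_yield,maize_lablab,kg/animal/day,8.3,13.1
milk_yield,oats_vetch,kg/animal/day,6.8,12.6
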