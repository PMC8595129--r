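species,body_weight_kg,cardiac_output_L_h,hematocrit,blood_volume_L
monkey,6,54,0.4,0.39
rat,0.25,5.4,0.46,0.016
human_chinese_male,60,300,0.45,4.62
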