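# Reference whole-body physiology compiled from standard compendia of
# organ weights and regional blood flows (Brown et al. 1997, Davies &
# Morris 1993), scaled to the stated body weight assuming unit density.
# species: human_chinese_male  body_weight_kg: 60  cardiac_output_L_h: 300  hematocrit: 0.45
tissue,volume_L,flow_L_per_h
heart,0.300,12.0
lung,0.480,300.0
brain,1.200,36.0
adipose,10.800,15.0
muscle,24.000,51.0
skin,2.220,15.0
spleen,0.156,9.0
reproductive,0.048,0.6
gut,1.020,48.0
liver,1.560,19.5
kidney,0.264,57.0
yellow_marrow,1.440,3.0
red_marrow,0.630,9.0
rest_of_body,6.000,24.9
arterial_blood,1.540,300.0
venous_blood,3.080,300.0
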