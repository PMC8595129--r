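# Reference whole-body physiology compiled from standard compendia of
# organ weights and regional blood flows (Brown et al. 1997, Davies &
# Morris 1993), scaled to the stated body weight assuming unit density.
# species: rat  body_weight_kg: 0.25  cardiac_output_L_h: 5.4  hematocrit: 0.46
tissue,volume_L,flow_L_per_h
heart,0.00082500000000000,0.2646
lung,0.00125000000000000,5.4000
brain,0.00142500000000000,0.1080
adipose,0.01750000000000000,0.3780
muscle,0.10100000000000001,1.5012
skin,0.04000000000000000,0.3132
spleen,0.00050000000000000,0.0540
reproductive,0.00062500000000000,0.0108
gut,0.00675000000000000,0.7074
liver,0.00915000000000000,0.1134
kidney,0.00182500000000000,0.7614
yellow_marrow,0.00250000000000000,0.0270
red_marrow,0.00375000000000000,0.1080
rest_of_body,0.02250000000000000,1.0530
arterial_blood,0.00533333333333333,5.4000
venous_blood,0.01066666666666667,5.4000
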