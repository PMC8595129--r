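# Reference whole-body physiology compiled from standard compendia of
# organ weights and regional blood flows (Brown et al. 1997, Davies &
# Morris 1993), scaled to the stated body weight assuming unit density.
# species: monkey  body_weight_kg: 6  cardiac_output_L_h: 54  hematocrit: 0.4
tissue,volume_L,flow_L_per_h
heart,0.024,2.700
lung,0.042,54.000
brain,0.090,3.780
adipose,0.600,2.160
muscle,2.700,7.560
skin,0.336,3.240
spleen,0.009,1.350
reproductive,0.006,0.108
gut,0.180,9.720
liver,0.150,3.510
kidney,0.030,9.180
yellow_marrow,0.090,0.540
red_marrow,0.072,1.890
rest_of_body,0.600,8.262
arterial_blood,0.130,54.000
venous_blood,0.260,54.000
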