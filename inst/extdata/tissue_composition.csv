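# Tissue composition for tissue-composition-based Kp prediction
# (Rodgers & Rowland 2005/2006 compilations, rat-derived reference values
# applied across species, as is conventional for these models).
# f_ew/f_iw: fractional extracellular/intracellular water; f_nl/f_np:
# fractional neutral lipid/neutral phospholipid; ap_mg_g: acidic
# phospholipid concentration (mg/g); protein_ratio: tissue:plasma ratio of
# the binding protein (albumin for acids/neutrals); ph_iw: intracellular pH.
tissue,f_ew,f_iw,f_nl,f_np,ap_mg_g,protein_ratio,ph_iw
adipose,0.135,0.017,0.846,0.0016,0.40,0.049,7.0
brain,0.162,0.620,0.039,0.0015,0.40,0.048,7.0
gut,0.282,0.475,0.0487,0.0163,2.41,0.158,7.0
heart,0.320,0.456,0.0115,0.0166,2.25,0.157,7.0
kidney,0.273,0.483,0.0207,0.0162,5.03,0.130,7.0
liver,0.161,0.573,0.0348,0.0252,4.56,0.086,7.0
lung,0.336,0.446,0.0219,0.0140,3.91,0.212,7.0
muscle,0.118,0.630,0.0238,0.0072,1.53,0.064,7.0
skin,0.382,0.291,0.0284,0.0111,1.32,0.277,7.0
spleen,0.207,0.579,0.0201,0.0198,3.18,0.097,7.0
reproductive,0.255,0.525,0.0048,0.0110,2.84,0.111,7.0
yellow_marrow,0.135,0.017,0.846,0.0016,0.40,0.049,7.0
red_marrow,0.100,0.340,0.017,0.0017,0.67,0.100,7.0
rest_of_body,0.250,0.500,0.050,0.0100,1.50,0.100,7.0
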