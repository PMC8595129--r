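# Body-surface-area dose-conversion factors (Km = body weight / BSA) from
# the standard regulatory animal-to-human dose conversion table, with the
# reference body weights they assume.
species,km,reference_bw_kg
mouse,3,0.02
rat,6,0.15
monkey,12,3
dog,20,10
human,37,60
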