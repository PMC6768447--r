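species,view,n_plants,n_days,n_angles,n_pairs,vis_width,vis_height,flu_width,flu_height
arabidopsis,top,4,20,1,80,2056,2454,1234,1624
wheat,side,4,47,3,564,1234,1624,1234,1624
maize,side,6,22,4,528,2056,2454,1038,1390
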