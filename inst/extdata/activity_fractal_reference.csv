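activity,d_tilde,d
falls,1.490,0.49
walking,0.518,
kneeling_down,0.554,
sitting_down,0.999,
standing_up,0.990,
picking_up_objects,0.699,
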