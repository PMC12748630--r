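task,type,n_subjects,n_samples
level_walk_short,All,64,312
level_walk_short,control,32,153
level_walk_short,patient,32,159
slow_blink_walk_long,All,62,1393
slow_blink_walk_long,control,31,690
slow_blink_walk_long,patient,31,703
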