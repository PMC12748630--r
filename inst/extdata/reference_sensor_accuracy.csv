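task,sensor,control,patient
level_walk_short,ankle_left,0.6337,0.5907
level_walk_short,ankle_right,0.5213,0.5903
level_walk_short,waist,0.5602,0.5119
level_walk_short,back,0.6122,0.6437
level_walk_short,head,0.5860,0.6215
level_walk_short,wrist,0.6896,0.7132
slow_blink_walk_long,ankle_left,0.6241,0.6138
slow_blink_walk_long,ankle_right,0.6493,0.6062
slow_blink_walk_long,waist,0.5980,0.6469
slow_blink_walk_long,back,0.6577,0.6711
slow_blink_walk_long,head,0.6132,0.5834
slow_blink_walk_long,wrist,0.7369,0.6868
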