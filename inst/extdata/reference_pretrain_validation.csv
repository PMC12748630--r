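dataset,sensor,performance
activity_windows,all,0.8796
pathology_cohort,ankle_left,0.7163
pathology_cohort,ankle_right,0.6744
pathology_cohort,waist,0.6986
pathology_cohort,back,0.6967
pathology_cohort,head,0.7600
pathology_cohort,wrist,0.7618
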