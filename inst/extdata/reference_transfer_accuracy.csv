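scenario,sensor,control,patient
activity_windows,ankle_left,0.6107,0.5684
activity_windows,ankle_right,0.5643,0.4172
activity_windows,waist,0.6395,0.5344
activity_windows,back,0.7005,0.5737
activity_windows,head,0.5506,0.4472
activity_windows,wrist,0.7639,0.6024
pathology_cohort,ankle_left,0.7604,0.7118
pathology_cohort,ankle_right,0.6427,0.6422
pathology_cohort,waist,0.7080,0.6376
pathology_cohort,back,0.6762,0.6778
pathology_cohort,head,0.6498,0.6198
pathology_cohort,wrist,0.7646,0.7684
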