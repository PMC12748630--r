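dataset,type,n_samples
activity_windows,All,1477
activity_windows,walking,882
activity_windows,running,595
pathology_cohort,All,313
pathology_cohort,control,57
pathology_cohort,patient,256
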