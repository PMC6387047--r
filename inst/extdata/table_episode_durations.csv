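patient,t_without_stim_s,t_with_stim_s,improvement_pct
Patient 1,7.74,4.52,41.63
Patient 2,9.87,9.22,6.59
Patient 3,10.19,6.83,33.02
Patient 4,7.04,5.92,15.87
Patient 5,7.18,4.97,30.84
Patient 6,4.56,3.06,32.89
Total,7.76,5.75,26.81
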