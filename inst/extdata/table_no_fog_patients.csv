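patient,signals_analyzed,tn,fp
Patient 7,15,14,1
Patient 8,15,12,3
Total,30,26,4
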