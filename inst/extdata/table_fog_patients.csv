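patient,episodes_diagnosed,tp,fn,resumptions
Patient 1,6,4,2,4
Patient 2,2,2,1,2
Patient 3,5,2,2,3
Patient 4,3,2,2,1
Patient 5,4,3,3,3
Patient 6,7,4,2,3
Total,27,20,13,16
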