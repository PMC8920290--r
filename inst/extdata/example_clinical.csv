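subject_id,time_months,event,age_dx,stage
subj01,48.2,1,61.5,III
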