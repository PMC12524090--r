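cell,count
both_correct,1265
baseline_wrong_model_correct,30
baseline_correct_model_wrong,15
both_wrong,1
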