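"individual_id","sex","age_y","weight_kg","height_cm","activity","survey_weight"
"I00001","male","60.2514659138396","70.788320114643","175.257128387360","moderate","0.789371086317646"
"I00002","female","61.2313181851059","67.042683231410","175.110542283262","low","1.210628913682354"
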