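band,pop,deaths
50-60,180,17
60-70,310,46
70-80,441,60
80-90,414,91
90-100,84,37
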