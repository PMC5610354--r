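band,n,observed_deaths
50-60,41,1
60-70,31,2
70-80,14,4
80-90,13,1
90-100,1,0
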