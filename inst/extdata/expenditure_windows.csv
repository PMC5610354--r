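window,variable,control_mean,control_ci_lower,control_ci_upper,test_mean,test_ci_lower,test_ci_upper,p_value
pre_start,pharma_cost,975.8,755,1205,919.4,748,1080,0.42
pre_start,total_cost,1931.7,1525,2339,2044,1648,2423,0.12
pre_end,pharma_cost,859.7,615,1149,505.9,318,770,0.001
pre_end,total_cost,1941.7,1366,2637,1038.2,656,1570,0.001
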