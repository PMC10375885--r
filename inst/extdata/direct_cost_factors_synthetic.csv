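income_class,factor
low,0.0958
lower_middle,0.08
upper_middle,0.06
high,0.044
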