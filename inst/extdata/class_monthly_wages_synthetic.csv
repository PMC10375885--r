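income_class,monthly_wage
low,104
lower_middle,300
upper_middle,800
high,3943.33
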