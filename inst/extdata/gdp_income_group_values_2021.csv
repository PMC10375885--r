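income_class,gdp_pc_ppp
high,48894
low,2327
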