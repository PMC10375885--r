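age_start,age_end,sex,prevalence
50,59,male,0.002
60,69,male,0.01
70,79,male,0.04
80,89,male,0.12
90,,male,0.25
50,59,female,0.0025
60,69,female,0.013
70,79,female,0.05
80,89,female,0.16
90,,female,0.35
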