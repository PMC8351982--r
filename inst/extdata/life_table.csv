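age_low,age_high,annual_mortality_probability
45,50,0.0032
50,55,0.0049
55,60,0.0074
60,65,0.0108
65,70,0.0162
70,75,0.0249
75,80,0.0390
80,85,0.0660
85,90,0.1120
90,95,0.1840
95,100,0.2750
100,120,0.3800
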