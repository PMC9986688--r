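# Synthetic female breast-cancer incidence fixture.
# Emulates the magnitude of recent England & Wales registry rates in
# 5-year bands; values are plausible, not the registry table itself.
# Half-open integer bands [age_low, age_high); rate per 100,000 person-years.
age_low,age_high,rate_per_100000
20,25,1.6
25,30,9.0
30,35,27.0
35,40,60.0
40,45,106.0
45,50,153.0
50,55,204.0
55,60,233.0
60,65,264.0
65,70,317.0
70,75,345.0
75,80,366.0
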