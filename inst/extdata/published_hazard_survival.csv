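# Published hourly hazard and survival probabilities of first attainment of
# the personal average daily MVPA in an observed adolescent cohort (N=113).
# Row "Before t" denotes the clock interval (t-1:00, t:00].
hour,label,hazard_prob,survival_prob
8,Before 8 AM,0.00,1.00
9,Before 9 AM,0.01,1.00
10,Before 10 AM,0.01,0.99
11,Before 11 AM,0.01,0.98
12,Before noon,0.01,0.97
13,Before 1 PM,0.02,0.96
14,Before 2 PM,0.03,0.94
15,Before 3 PM,0.03,0.91
16,Before 4 PM,0.04,0.88
17,Before 5 PM,0.05,0.85
18,Before 6 PM,0.05,0.81
19,Before 7 PM,0.05,0.77
20,Before 8 PM,0.04,0.73
21,Before 9 PM,0.04,0.70
22,Before 10 PM,0.03,0.68
23,Before 11 PM,0.00,0.66
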