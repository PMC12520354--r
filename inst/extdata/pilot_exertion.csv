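participant,age_years,avg_hr_bpm,peak_hr_bpm,peak_rpe
Y1,14,154,184,5
Y2,14,128,155,4
Y3,13,172,196,7
Y4,13,137,156,2
Y5,15,NA,155,3
Y6,21,117,152,2
Y7,22,155,184,5
Y8,15,115,132,4
Y9,22,NA,158,2
Y10,10,134,163,6
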