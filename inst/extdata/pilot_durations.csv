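session,configuration_min,active_min,total_min
1,5.38,41.48,46.86
2,6.05,25.49,31.54
3,4.42,27.32,31.74
4,7.53,25.16,32.69
5,3.46,24.33,27.79
6,5.97,23.27,29.24
7,6.34,29.58,35.92
8,5.76,23.27,29.03
9,6.16,28.44,34.60
10,6.93,24.25,31.18
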