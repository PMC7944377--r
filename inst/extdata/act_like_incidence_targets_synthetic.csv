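band_start,rate_per_1000py
50,0.2
55,0.5
60,1
65,2.2
70,4.8
75,10.5
80,21
85,41
90,80
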