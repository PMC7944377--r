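band_start,sex,s5
50,man,0.937562819491613
50,woman,0.944470330067198
55,man,0.907622981047257
55,woman,0.916897932564341
60,man,0.864401041236001
60,woman,0.876558041695465
65,man,0.803263476108687
65,woman,0.818666020720363
70,man,0.719389257230165
70,woman,0.737978950027982
75,man,0.609481042291168
75,woman,0.630393376350219
80,man,0.475018005727046
80,woman,0.496238359685562
85,man,0.326563229898321
85,woman,0.345044796239606
90,man,0.185909018659916
90,woman,0.198709176738925
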