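age_min,age_max,edu_min,edu_max,tmta_cutoff
18,34,0,8,45
18,34,9,12,40
18,34,13,30,38
35,54,0,8,48
35,54,9,12,43
35,54,13,30,40
55,120,0,8,58
55,120,9,12,52
55,120,13,30,47
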