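pesticide,cluster,center_d,center_dbar,sample_size,quality_level
dimethoate,1,0.03950035,0.03341637,810,1
dimethoate,2,0.04434314,0.03039072,1080,2
dimethoate,3,0.04900005,0.04175411,765,3
chlorpyrifos,1,0.22891236,0.17001536,855,1
chlorpyrifos,2,0.28989454,0.20340521,765,2
chlorpyrifos,3,0.33112902,0.25336484,1035,3
chlorpyrifos-methyl,1,1.77091609,1.22453220,890,1
chlorpyrifos-methyl,2,2.43346228,1.54720279,935,2
chlorpyrifos-methyl,3,3.20258731,2.02372957,830,3
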