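object_id,conf_Cdv,conf_Cbc,conf_Rad,conf_dtm,conf_oth
1,0.87,0.08,0.03,0.00,0.01
2,0.20,0.00,0.79,0.00,0.01
3,0.00,0.00,0.00,1.00,0.00
4,0.00,0.00,0.01,0.98,0.01
5,0.00,0.00,0.92,0.07,0.00
500,0.01,0.59,0.03,0.09,0.28
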