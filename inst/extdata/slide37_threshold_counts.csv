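threshold,Cdv,Cbc,Rad,dtm,oth
0.60,70,8,204,154,17
0.95,31,0,117,111,3
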