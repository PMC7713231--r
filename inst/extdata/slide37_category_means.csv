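category,mean_confidence
Cdv,0.16
Cbc,0.02
Rad,0.44
dtm,0.33
oth,0.05
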