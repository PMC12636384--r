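cancer_type,tp,fp,fn,tn,prevalence_per_100k
CRC,489,2,411,1778,247
GC,324,2,202,1778,99
EC,84,2,40,1778,21
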