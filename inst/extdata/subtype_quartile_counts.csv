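subtype,Q1,Q2,Q3,Q4
LAA,58,92,89,71
CE,19,37,32,32
SAA,115,98,84,61
Other,28,23,20,17
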