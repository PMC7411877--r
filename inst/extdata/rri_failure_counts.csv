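subject,total_rri,outliers
A,245920,11564
B,163520,577
C,159240,5805
D,474630,31665
E,343770,14668
F,144530,2446
G,419440,11866
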