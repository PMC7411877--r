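subject,statistic,group,rate_per_h
A,Q,patient,3.34
B,Q,patient,0.29
C,Q,patient,1.62
D,Q,patient,0.43
E,Q,patient,0.67
F,Q,patient,0.73
G,Q,patient,0.74
A,T2,patient,1.11
B,T2,patient,1.16
C,T2,patient,1.62
D,T2,patient,1.71
E,T2,patient,0.34
F,T2,patient,4.76
G,T2,patient,0.37
A,Q,control,0
B,Q,control,0
C,Q,control,0.69
D,Q,control,0.14
E,Q,control,1.32
F,Q,control,1.30
G,Q,control,0.97
A,T2,control,2.14
B,T2,control,1.46
C,T2,control,1.92
D,T2,control,0.56
E,T2,control,0.59
F,T2,control,0.65
G,T2,control,1.82
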