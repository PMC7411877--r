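seizure_id,statistic,start_s,end_s
A1,Q,-310,-298
A2,Q,-316,-139
A3,Q,NA,NA
B1,Q,-426,-316
C1,Q,-880,-865
C1,Q,-761,-700
C2,Q,NA,NA
D1,Q,-785,-675
E1,Q,-969,-884
E1,Q,-576,-399
E2,Q,-883,-636
F1,Q,-763,-726
F2,Q,-941,-762
F2,Q,-613,-524
G1,Q,-863,-819
G1,Q,-517,-294
G1,Q,-218,-65
G2,Q,-232,-179
G3,Q,-738,-573
A1,T2,NA,NA
A2,T2,NA,NA
A3,T2,NA,NA
B1,T2,NA,NA
C1,T2,NA,NA
C2,T2,-596,-496
D1,T2,NA,NA
E1,T2,NA,NA
E2,T2,NA,NA
F1,T2,-798,-628
F1,T2,-394,-172
F2,T2,NA,NA
G1,T2,NA,NA
G2,T2,NA,NA
G3,T2,NA,NA
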