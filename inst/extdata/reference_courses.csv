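patient_id,group,total_dose_gy,n1,dose1_gy,n2,dose2_gy,bed10_gy,days_to_finish
L1,L,75,30,2.5,NA,NA,93.8,46
L2,L,75,30,2.5,NA,NA,93.8,43
L3,L,75,30,2.5,NA,NA,93.8,44
L4,L,80,20,2.5,15,2,98.5,70
L5,L,66.6,37,1.8,NA,NA,78.6,55
S1,S,50,5,10,NA,NA,100.0,12
S2,S,50,5,10,NA,NA,100.0,9
S3,S,50,5,10,NA,NA,100.0,9
S4,S,50,5,10,NA,NA,100.0,11
S5,S,50,5,10,NA,NA,100.0,12
S6,S,50,5,10,NA,NA,100.0,12
S7,S,50,5,10,NA,NA,100.0,12
S8,S,50,5,10,NA,NA,100.0,9
S10,S,50,5,10,NA,NA,100.0,9
S11,S,50,5,10,NA,NA,100.0,11
S12,S,50,5,10,NA,NA,100.0,9
S13,S,50,5,10,NA,NA,100.0,9
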