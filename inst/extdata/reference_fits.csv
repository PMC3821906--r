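patient_id,group,rank,model,response_type,V0_cc,Td,GF,Tpot,gamma,gamma_rec,K,Kp,Kq,D,Rini,Rind_pct,delta_pct,rec_start,rec_end
L1,L,1,MRes,B,8.5,200,NA,5.6,NA,NA,15,NA,NA,0.5,0.20,3.4,8.0,NA,NA
L1,L,2,StRec,B,8.5,200,0.15,13.9,0.01,0.10,NA,29,1,0.56,NA,NA,7.0,22,NA
L2,L,1,M,C,13.2,100,NA,9.3,NA,NA,1.8,NA,NA,0.2,NA,NA,3.5,NA,NA
L3,L,1,StRec,B,4.6,400,0.05,27.8,0,0.37,NA,49,1,0.6,NA,NA,10.2,1,13
L4,L,1,MRes,A,161.1,1000,NA,5.5,NA,NA,10,NA,NA,0.3,0.31,3.2,4.0,NA,NA
L5,L,1,MRes,A,1.8,150,NA,5.6,NA,NA,16,NA,NA,0.35,0.36,6.2,5.1,NA,NA
L5,L,2,StRec,A,1.8,150,0.25,5.6,0,0.02,NA,7,1,0.36,NA,NA,5.4,15,NA
S1,S,1,St,A,3.2,25,0.06,22.8,0,NA,NA,90,5,0.2,NA,NA,8.4,NA,NA
S2,S,1,StRec,B,12.1,25,0.10,14.3,0,0.26,NA,90,1,1,NA,NA,6.8,1,3
S3,S,1,M,D,2.0,250,NA,5.6,NA,NA,8,NA,NA,0.999,NA,NA,6.6,NA,NA
S4,S,1,M,C,2.0,NA,NA,NA,NA,NA,25,NA,NA,NA,NA,NA,4.0,NA,NA
S5,S,1,M,C,23.5,150,NA,8.4,NA,NA,9,NA,NA,0.2,NA,NA,3.7,NA,NA
S5,S,2,St,C,23.5,150,NA,8.4,NA,NA,NA,90,2,0.2,NA,NA,5.1,NA,NA
S6,S,1,M,D,8.1,45,NA,5.6,NA,NA,13,NA,NA,1,NA,NA,6.6,NA,NA
S7,S,1,St,A,4.7,30,0.06,23.6,0,NA,NA,99,23,0.2,NA,NA,9.2,NA,NA
S8,S,1,StRec,B,1.2,1000,0.05,27.7,0,0.48,NA,65,1,0.9,NA,NA,7.2,1,3
S10,S,1,St,A,3.2,15,NA,9.7,0.01,NA,NA,99,23,0.2,NA,NA,13.1,NA,NA
S11,S,1,M,D,1.7,15,NA,5.8,NA,NA,22,NA,NA,0.99,NA,NA,23.9,NA,NA
S12,S,1,StRec,B,0.7,75,0.05,28.0,0,0.74,NA,76,0.01,0.75,NA,NA,7.2,1,3
S13,S,1,St,A,4.1,1000,NA,5.5,NA,NA,NA,90,53,0.2,NA,NA,14.6,NA,NA
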