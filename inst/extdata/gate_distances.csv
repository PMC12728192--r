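pair,a,b,loop,slot,residue_a,residue_b,distance
cl-op,cl,op,L1,1,T144,T144,14.25
cl-op,cl,op,L1,2,D145,D145,19.25
cl-op,cl,op,L1,3,S152,S152,12.13
cl-op,cl,op,L1,4,A153,A153,10.93
cl-daro,cl,daro,L1,1,T144,T144,10.93
cl-daro,cl,daro,L1,2,D145,D145,12.99
cl-daro,cl,daro,L1,3,S152,S152,11.34
cl-daro,cl,daro,L1,4,A153,A153,9.60
op-daro,op,daro,L1,1,T144,T144,5.15
op-daro,op,daro,L1,2,D145,D145,7.97
op-daro,op,daro,L1,3,S152,S152,3.28
op-daro,op,daro,L1,4,A153,A153,3.39
daro-stall,daro,stall,L1,1,T144,T129,8.58
daro-stall,daro,stall,L1,2,D145,N130,10.78
daro-stall,daro,stall,L1,3,S152,E138,7.55
daro-stall,daro,stall,L1,4,A153,A139,6.20
op-stall,op,stall,L1,1,T144,T129,4.30
op-stall,op,stall,L1,2,D145,N130,3.22
op-stall,op,stall,L1,3,S152,E138,6.09
op-stall,op,stall,L1,4,A153,A139,4.26
cl-stall,cl,stall,L1,1,T144,T129,18.45
cl-stall,cl,stall,L1,2,D145,N130,22.27
cl-stall,cl,stall,L1,3,S152,E138,18.14
cl-stall,cl,stall,L1,4,A153,A139,15.09
cl-op,cl,op,L2,1,A173,A173,4.64
cl-op,cl,op,L2,2,S174,S174,6.30
cl-op,cl,op,L2,3,A182,A182,4.56
cl-op,cl,op,L2,4,Y183,Y183,2.91
cl-daro,cl,daro,L2,1,A173,A173,4.74
cl-daro,cl,daro,L2,2,S174,S174,5.98
cl-daro,cl,daro,L2,3,A182,A182,4.76
cl-daro,cl,daro,L2,4,Y183,Y183,3.11
op-daro,op,daro,L2,1,A173,A173,1.15
op-daro,op,daro,L2,2,S174,S174,1.11
op-daro,op,daro,L2,3,A182,A182,0.30
op-daro,op,daro,L2,4,Y183,Y183,0.44
daro-stall,daro,stall,L2,1,A173,I162,1.63
daro-stall,daro,stall,L2,2,S174,L163,2.64
daro-stall,daro,stall,L2,3,A182,S171,1.31
daro-stall,daro,stall,L2,4,Y183,F172,0.83
op-stall,op,stall,L2,1,A173,I162,1.69
op-stall,op,stall,L2,2,S174,L163,2.10
op-stall,op,stall,L2,3,A182,S171,1.29
op-stall,op,stall,L2,4,Y183,F172,1.13
cl-stall,cl,stall,L2,1,A173,I162,5.99
cl-stall,cl,stall,L2,2,S174,L163,8.36
cl-stall,cl,stall,L2,3,A182,S171,4.93
cl-stall,cl,stall,L2,4,Y183,F172,3.43
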