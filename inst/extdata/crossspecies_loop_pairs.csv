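loop,slot,chain_a,resseq_a,res_a,chain_b,resseq_b,res_b
L1,1,A,144,THR,A,129,THR
L1,2,A,145,ASP,A,130,ASN
L1,3,A,152,SER,A,138,GLU
L1,4,A,153,ALA,A,139,ALA
L2,1,A,173,ALA,A,162,ILE
L2,2,A,174,SER,A,163,LEU
L2,3,A,182,ALA,A,171,SER
L2,4,A,183,TYR,A,172,PHE
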