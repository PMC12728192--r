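res_name,atom,role
DAR,N1,donor
DAR,N2,donor
DAR,N3,donor
DAR,N4,donor
DAR,N5,donor
DAR,N6,donor
DAR,N7,donor
DAR,O1,acceptor
DAR,O2,acceptor
DAR,O3,acceptor
DAR,O4,acceptor
DAR,O5,acceptor
DAR,O6,acceptor
DAR,O7,acceptor
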