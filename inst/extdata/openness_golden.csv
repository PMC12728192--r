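pair,loop,d1,d2,d3,d4,mean_display,percent_display
cl-op,L1,14.25,19.25,12.13,10.93,14.14,76.48
cl-op,L2,4.64,6.3,4.56,2.91,4.60,81.06
cl-daro,L1,10.93,12.99,11.34,9.6,11.21,60.66
cl-daro,L2,4.74,5.98,4.76,3.11,4.64,81.85
op-daro,L1,5.15,7.97,3.28,3.39,4.94,26.76
op-daro,L2,1.15,1.11,0.3,0.44,0.75,13.21
daro-stall,L1,8.58,10.78,7.55,6.2,8.27,44.77
daro-stall,L2,1.63,2.64,1.31,0.83,1.60,28.22
op-stall,L1,4.3,3.22,6.09,4.26,4.46,24.16
op-stall,L2,1.69,2.1,1.29,1.13,1.55,27.34
cl-stall,L1,18.45,22.27,18.14,15.09,18.48,100.00
cl-stall,L2,5.99,8.36,4.93,3.43,5.67,100.00
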