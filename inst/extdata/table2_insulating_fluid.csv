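# n=19 m=8 R=0,0,3,0,3,0,0,5
# model=rayleigh
r,x,R
1,0.19,0
2,0.78,0
3,0.96,3
4,1.31,0
5,2.78,3
6,4.85,0
7,6.5,0
8,7.35,5
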