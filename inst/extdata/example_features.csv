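hw,hmax,sigma,p40,label
0.62,0.28,385,0.74,isLy
0.85,0.35,295,0.81,isLy
0.49,0.22,310,0.69,isLy
3.05,0.96,271,0.12,notLy
2.02,0.88,288,0.09,notLy
2.80,1.00,249,0.16,notLy
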