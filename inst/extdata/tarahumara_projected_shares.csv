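class,epoch,share_pct
AWV,2017,4.848
SF,2017,57.716
HS,2017,0.105
WB,2017,0.031
PF,2017,37.300
AWV,2050s,5.275
SF,2050s,73.721
HS,2050s,0.105
WB,2050s,0.031
PF,2050s,20.868
AWV,2050o,5.017
SF,2050o,61.863
HS,2050o,0.105
WB,2050o,0.031
PF,2050o,32.983
AWV,2050p,7.695
SF,2050p,83.628
HS,2050p,0.105
WB,2050p,0.031
PF,2050p,8.541
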