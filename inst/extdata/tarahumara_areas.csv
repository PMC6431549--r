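class,epoch,area_ha
AWV,1990,20444.18
SF,1990,199121.38
HS,1990,154.60
WB,1990,26.9712
PF,1990,277380.46
AWV,2005,23828.59
SF,2005,223948.16
HS,2005,272.35
WB,2005,103.76
PF,2005,248973.97
AWV,2017,24101.92
SF,2017,286922.04
HS,2017,521.65
WB,2017,153.91
PF,2017,185427.79
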