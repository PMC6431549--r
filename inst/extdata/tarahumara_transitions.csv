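period,from,AWV,SF,HS,WB,PF
1990-2005,AWV,0.9000,0.0250,0.0250,0.0250,0.0250
1990-2005,SF,0.0222,0.7516,0.0008,0.0005,0.2248
1990-2005,HS,0.0452,0.0645,0.8806,0.0000,0.0097
1990-2005,WB,0.0000,0.1254,0.0000,0.8553,0.0193
1990-2005,PF,0.0020,0.2865,0.0000,0.0000,0.7115
2005-2017,AWV,0.6250,0.3504,0.0108,0.0029,0.0109
2005-2017,SF,0.0557,0.8116,0.0004,0.0000,0.1323
2005-2017,HS,0.0557,0.2479,0.6959,0.0000,0.0004
2005-2017,WB,0.0095,0.1684,0.0000,0.8030,0.0191
2005-2017,PF,0.0056,0.3798,0.0003,0.0000,0.6144
1990-2017,AWV,0.6615,0.3124,0.0120,0.0035,0.0106
1990-2017,SF,0.0654,0.7945,0.0012,0.0006,0.1384
1990-2017,HS,0.0651,0.0774,0.8575,0.0000,0.0000
1990-2017,WB,0.0000,0.1868,0.0000,0.7957,0.0175
1990-2017,PF,0.0071,0.4419,0.0002,0.0000,0.5508
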