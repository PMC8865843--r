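"curve","frequency_hz","sensitivity"
"RA",5,2e-04
"RA",6,6e-04
"RA",7,0.0017
"RA",8,0.0039
"RA",9,0.0078
"RA",10,0.0139
"RA",11,0.0227
"RA",12,0.0346
"RA",14,0.0689
"RA",15,0.0913
"RA",17,0.1465
"RA",19,0.2134
"RA",22,0.3291
"RA",24,0.4116
"RA",27,0.5354
"RA",30,0.6514
"RA",34,0.7842
"RA",38,0.8854
"RA",43,0.9658
"RA",48,1
"RA",53,0.9971
"RA",60,0.9491
"RA",67,0.8704
"RA",75,0.7642
"RA",84,0.6427
"RA",94,0.519
"RA",105,0.4037
"RA",118,0.2964
"RA",132,0.2112
"RA",147,0.1467
"RA",165,0.095
"RA",185,0.0592
"RA",207,0.0357
"RA",231,0.0209
"RA",259,0.0115
"RA",290,0.0061
"RA",325,0.0031
"RA",363,0.0015
"RA",407,7e-04
"RA",455,3e-04
"RA",510,1e-04
"RA",570,1e-04
"RA",638,0
"RA",715,0
"RA",800,0
"PC",5,0
"PC",6,0
"PC",7,0
"PC",8,0
"PC",9,0
"PC",10,0
"PC",11,0
"PC",12,0
"PC",14,0
"PC",15,0
"PC",17,0
"PC",19,0
"PC",22,0
"PC",24,0
"PC",27,0
"PC",30,0
"PC",34,0
"PC",38,1e-04
"PC",43,2e-04
"PC",48,5e-04
"PC",53,0.0012
"PC",60,0.0033
"PC",67,0.0073
"PC",75,0.0156
"PC",84,0.0312
"PC",94,0.0585
"PC",105,0.1021
"PC",118,0.1719
"PC",132,0.2663
"PC",147,0.3823
"PC",165,0.5287
"PC",185,0.6831
"PC",207,0.8251
"PC",231,0.9342
"PC",259,0.9981
"PC",290,1
"PC",325,0.9399
"PC",363,0.8325
"PC",407,0.689
"PC",455,0.5385
"PC",510,0.3926
"PC",570,0.2712
"PC",638,0.1752
"PC",715,0.1057
"PC",800,0.0603
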