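W,N1,N2,N3,REM
41458,1222,2261,260,900
1706,4221,2857,24,1460
2397,1534,120994,11945,4725
409,2,8896,50471,230
1562,615,4824,346,58481
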