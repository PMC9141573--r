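W,N1,N2,N3,REM
7873,46,13,7,6
50,388,105,4,52
8,49,3230,234,55
3,0,104,1191,1
14,24,96,3,1444
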