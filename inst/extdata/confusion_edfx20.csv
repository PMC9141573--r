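W,N1,N2,N3,REM
7585,291,102,20,88
363,1291,673,12,429
336,382,15596,741,554
29,1,663,4914,2
133,194,491,0,6860
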