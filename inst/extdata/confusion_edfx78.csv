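W,N1,N2,N3,REM
61212,3406,506,44,462
3359,9744,6568,133,1683
539,3097,58825,4259,2276
20,22,2580,10360,8
608,1199,2263,59,21618
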