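x1,x2,cog_obs,is_expectation
0.5,-1.2,1.75,TRUE
-0.25,2,3.5,FALSE
1,0,0.125,TRUE
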