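component,s1,s2,s3,s4,s5,e,f,r2,rmse
trunk,0.2124,0.1964,0.1904,0.2517,0.2438,1.8021,0.2035,0.7042,13.6057
bark,0.1098,0.1016,0.0991,0.1289,0.1242,1.4594,0.2122,0.6927,2.2191
branch,0.2901,0.2662,0.2634,0.3614,0.3392,1.1792,0.2989,0.6345,3.4749
leaf,0.3401,0.3522,0.3464,0.4599,0.4372,0.9358,0.2524,0.5316,1.7175
total,NA,NA,NA,NA,NA,NA,NA,0.6835,20.9835
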