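form,component,a,b,c,d,se_a,se_b,se_c,se_d,aic,bic,r2_train,rmse_train,tre_train,r2_test,rmse_test,tre_test
logistic,bark,152.4712,74.0495,0.1849,0.1210,3.0908,1.6807,0.0025,0.0036,118516,118554,0.6968,14.0616,14.7311,0.7017,13.8441,14.0853
logistic,trunk,23.0897,51.4099,0.1729,0.1297,0.4412,1.0812,0.0024,0.0037,64684,64721,0.6938,2.2213,12.2229,0.6981,2.1869,12.2229
logistic,branch,31.6152,37.0484,0.1477,0.1911,0.6479,0.8338,0.0024,0.0048,78855,78893,0.6172,3.6106,15.9090,0.6209,3.5423,15.0717
logistic,leaf,12.0925,13.1769,0.1164,0.2228,0.2203,0.2831,0.0025,0.0062,57095,57133,0.5346,1.7125,12.1670,0.5355,1.6915,11.7104
logistic,total,222.2174,54.6878,0.1699,0.1358,4.5191,1.1468,0.0023,0.0037,130137,130175,0.6862,20.9428,13.6838,0.6911,20.5834,13.0369
linear,bark,4.4580,3.4427,-36.5957,NA,0.0326,0.0891,0.4069,NA,119805,119835,0.6687,14.6976,16.3161,0.6751,14.4483,15.5760
linear,trunk,0.6944,0.5907,-5.2291,NA,0.0051,0.0138,0.0633,NA,65453,65483,0.6772,2.2808,13.5626,0.6728,2.2417,12.9435
linear,branch,0.8556,1.2093,-6.2027,NA,0.0081,0.0221,0.1011,NA,79155,79185,0.6092,3.6481,16.2959,0.6145,3.5723,15.3925
linear,leaf,0.3155,0.5897,-0.9447,NA,0.0038,0.0104,0.0476,NA,57008,57038,0.5373,1.7075,12.0880,0.5392,1.6846,11.6163
linear,total,6.3235,5.8324,-48.9722,NA,0.0479,0.1311,0.5986,NA,131043,131073,0.6660,21.6046,14.6914,0.6723,21.2003,13.9661
exponential,bark,5.2187,-0.1140,-0.0580,NA,0.0672,0.0007,0.0016,NA,119897,119927,0.6666,14.7439,16.4360,0.6772,14.4000,15.4322
exponential,trunk,1.0704,-0.1033,-0.5915,NA,0.0126,0.0007,0.0016,NA,66102,66133,0.6624,2.3322,14.2688,0.6715,2.2812,13.4594
exponential,branch,1.8708,-0.0884,-0.0819,NA,0.0241,0.0008,0.0017,NA,80057,80087,0.5843,3.7627,17.5174,0.5933,3.6692,16.4382
exponential,leaf,1.8960,-0.1027,-0.0517,NA,0.0178,0.0007,0.0016,NA,80235,80266,0.6736,3.7858,12.9121,0.6814,3.7180,12.2863
exponential,total,9.4116,-0.1045,-0.0634,NA,0.1147,0.0008,0.0016,NA,131449,131479,0.6566,21.9076,15.1694,0.6668,21.3776,14.2346
power,bark,0.1312,2.0123,0.1932,NA,0.0051,0.0136,0.0051,NA,118537,118567,0.6963,14.0724,14.7571,0.7133,13.8063,13.9398
power,trunk,0.0636,1.8773,0.1752,NA,0.0015,0.0124,0.0047,NA,83695,83726,0.6994,2.2056,13.0076,0.7052,2.2386,12.3850
power,branch,0.1302,1.4902,0.2832,NA,0.0003,0.0191,0.0066,NA,78998,79028,0.6134,3.6286,16.0935,0.6175,3.5583,15.2033
power,leaf,0.3362,0.9419,0.2484,NA,0.0102,0.0112,0.0049,NA,57404,57434,0.5246,1.7308,12.4618,0.5234,1.7133,12.0541
power,total,0.3551,1.8102,0.2109,NA,0.0129,0.0129,0.0049,NA,130208,130238,0.6846,20.9950,13.7616,0.6909,20.5870,12.9989
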