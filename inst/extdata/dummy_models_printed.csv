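component,a1,a2,a3,a4,a5,b,c,se_a1,se_a2,se_a3,se_a4,se_a5,se_b,se_c,r2_train,rmse_train,tre_train,r2_test,rmse_test,tre_test
bark,0.2221,0.2034,0.1929,0.2582,0.2524,1.8152,0.1936,0.0094,0.0097,0.0093,0.0129,0.0123,0.0178,0.0049,0.7193,13.5287,13.4880,0.7198,13.4717,13.0373
trunk,0.0682,0.0627,0.0598,0.0781,0.0763,1.6104,0.1939,0.0027,0.0026,0.0027,0.0036,0.0035,0.0164,0.0046,0.7147,2.1441,11.7994,0.7140,2.1287,11.4484
branch,0.2290,0.2088,0.2024,0.2756,0.2635,1.2731,0.2870,0.0099,0.0098,0.0101,0.0141,0.0132,0.0181,0.0055,0.6434,3.4849,14.6613,0.6403,3.4507,14.1326
leaf,0.4902,0.4537,0.4476,0.5695,0.5447,0.7961,0.2508,0.0176,0.0175,0.0187,0.0246,0.0231,0.0151,0.0048,0.5533,1.6777,11.6213,0.5461,1.6720,11.3978
total,0.5919,0.5405,0.5156,0.6873,0.6685,1.6189,0.2122,0.0241,0.0238,0.0241,0.0329,0.0314,0.0169,0.0048,0.7095,20.1484,12.5377,0.7091,19.9734,12.1172
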