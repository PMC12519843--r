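age_group,sample,component,max,min,mean,sd,typo_flag,additive_row
1,train,bark,13.1381,0.1096,3.3632,2.1627,none,TRUE
1,train,trunk,82.1074,0.4052,17.8427,12.5648,none,TRUE
1,train,branch,24.0875,0.1859,5.4190,3.5186,none,TRUE
1,train,leaf,12.6573,0.2178,3.6598,1.8578,none,TRUE
1,train,total,121.232,1.032,30.285,19.8221,none,TRUE
1,test,bark,13.6484,0.1078,3.3480,2.1404,none,TRUE
1,test,trunk,82.2535,0.3908,17.7663,12.3915,none,TRUE
1,test,branch,20.7011,0.1999,5.3753,3.5153,none,TRUE
1,test,leaf,11.6341,0.3181,3.6286,1.8696,none,TRUE
1,test,total,126.284,1.0660,30.118,19.63353,none,TRUE
2,train,bark,27.7597,0.1905,4.2946,2.6693,none,TRUE
2,train,trunk,114.5734,0.2389,23.7724,16.2536,none,TRUE
2,train,branch,27.7597,0.1905,6.3721,4.0636,none,TRUE
2,train,leaf,13.1418,0.3621,3.9614,1.9822,none,TRUE
2,train,total,167.7102,0.9027,38.4005,24.5177,none,TRUE
2,test,bark,18.4729,0.1616,4.2767,2.7001,none,TRUE
2,test,trunk,117.290,0.664,23.706,16.5119,none,TRUE
2,test,branch,26.7768,0.1962,6.3189,4.0678,none,TRUE
2,test,leaf,12.3967,0.2959,3.9307,1.9809,none,TRUE
2,test,total,172.002,1.3180,38.2320,24.7832,none,TRUE
3,train,bark,18.203,0.2100,5.6330,3.1345,none,FALSE
3,train,trunk,119.9051,0.8125,5.6330,19.4172,mean_duplicates_bark,FALSE
3,train,branch,30.9941,0.3836,8.1419,4.7029,none,FALSE
3,train,leaf,13.8340,0.5250,4.6920,2.1299,none,FALSE
3,train,total,172.8820,1.9910,50.5760,28.9169,none,FALSE
3,test,bark,17.3344,0.2384,5.6755,3.2327,none,FALSE
3,test,trunk,119.5493,32.4140,32.4140,20.2089,min_equals_mean,FALSE
3,test,branch,28.8945,0.3809,8.1836,4.7461,none,FALSE
3,test,leaf,13.3614,0.5477,4.7083,2.1188,none,FALSE
3,test,total,170.803,2.126,50.9810,29.8144,none,FALSE
4,train,bark,30.2370,0.3516,9.6597,5.0867,none,TRUE
4,train,trunk,202.511,1.415,58.025,33.8275,none,TRUE
4,train,branch,43.9100,0.6700,13.9670,7.3899,none,TRUE
4,train,leaf,20.7530,0.8990,6.9680,2.8834,none,TRUE
4,train,total,288.847,3.3350,88.6200,48.1882,none,TRUE
4,test,bark,29.1160,0.5170,9.6740,5.1307,none,FALSE
4,test,trunk,202.1930,2.2330,9.6740,34.2114,mean_duplicates_bark,FALSE
4,test,branch,41.6285,0.5713,13.9616,7.4742,none,FALSE
4,test,leaf,17.8720,0.6087,6.9545,2.9362,none,FALSE
4,test,total,276.6640,4.1920,88.7440,48.6847,none,FALSE
5,train,bark,28.2904,0.3132,8.9868,5.1823,none,FALSE
5,train,trunk,196.453,1.1780,54.831,34.1049,none,FALSE
5,train,branch,41.3550,0.5135,6.4952,7.3607,mean_duplicates_leaf,FALSE
5,train,leaf,16.7751,0.7119,6.4952,2.8506,none,FALSE
5,train,total,279.8830,2.6970,82.1660,48.7637,none,FALSE
5,test,bark,32.9320,0.2010,8.9860,5.1799,none,TRUE
5,test,trunk,219.7082,0.7777,53.8313,34.1237,none,TRUE
5,test,branch,47.2662,0.3596,12.9217,7.4495,none,TRUE
5,test,leaf,17.1669,0.4503,6.5330,2.9408,none,TRUE
5,test,total,316.848,1.891,82.272,48.8275,none,TRUE
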