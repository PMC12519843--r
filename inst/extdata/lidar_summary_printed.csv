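metric,sample,max,min,mean,sd
lh,train,31.6296,2.9455,13.1114,4.0801
lh,test,28.771,2.7577,13.1416,4.0674
lcd,train,16.474,0.13624,2.3081,1.4899
lcd,test,12.046,0.1612,2.3401,1.5169
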