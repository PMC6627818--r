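origin,temperature,n,fit,sd,se,ci
SC,5,11,28.6,5.7,1.7,3.8
SC,10,11,33.1,4.5,1.4,3.1
SC,15,11,53.8,7.1,2.1,4.8
VA,5,10,34.0,5.7,1.8,4.1
VA,10,10,45.2,7.8,2.5,5.6
VA,15,10,72.5,10.0,3.2,7.2
SC,20,5,86.6,13.4,6.0,16.6
SC,25,5,135.1,24.3,10.9,30.1
SC,30,5,231.7,29.4,13.1,36.5
VA,20,10,100.2,10.7,3.4,7.7
VA,25,10,185.6,38.3,12.1,27.4
VA,30,10,291.7,59.4,18.8,42.5
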