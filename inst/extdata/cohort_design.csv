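line,sex,genotype,n
IL72,M,0,8
IL72,M,1,11
IL72,F,0,14
IL72,F,1,8
IL188,M,0,5
IL188,M,1,8
IL188,F,0,3
IL188,F,1,8
IL2513,M,0,8
IL2513,M,1,3
IL2513,F,0,4
IL2513,F,1,12
IL2750,M,0,6
IL2750,M,1,7
IL2750,F,0,6
IL2750,F,1,11
IL3348,M,0,10
IL3348,M,1,9
IL3348,F,0,12
IL3348,F,1,13
IL5000,M,0,14
IL5000,M,1,10
IL5000,F,0,9
IL5000,F,1,12
IL5008,M,0,9
IL5008,M,1,12
IL5008,F,0,13
IL5008,F,1,11
IL6009,M,0,6
IL6009,M,1,10
IL6009,F,0,10
IL6009,F,1,5
IL6012,M,0,10
IL6012,M,1,9
IL6012,F,0,6
IL6012,F,1,11
IL6018,M,0,16
IL6018,M,1,18
IL6018,F,0,19
IL6018,F,1,15
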