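analysis,effect,conv_df,shape_df,ss,ms,f
A1,individual,9,90,0.111301,0.001237,125.639
A1,part,4,40,0.000429,0.000011,1.090
A1,interaction,36,360,0.003544,0.000010,3.377
A1,error,50,500,0.001457,0.000003,NA
size,individual,9,9,141.697309,15.744145,1353.196
size,part,4,4,0.037473,0.009368,0.805
size,interaction,36,36,0.418852,0.011635,7.807
size,error,50,50,0.074512,0.001490,NA
A2,part,4,40,0.000429,0.000011,3.312
A2,reflection,1,10,0.010059,0.001006,365.744
A2,interaction,4,40,0.000605,0.000015,5.497
A2,symmetricError,45,450,0.001457,0.000003,NA
A2,asymmetricError,45,450,0.001238,0.000003,NA
A2,totalError,45,900,0.002695,0.000003,NA
A3,individual,9,90,0.111274,0.001236,125.648
A3,part,4,40,0.000429,0.000011,1.090
A3,reflectionInPart,5,50,0.010664,0.000213,12.511
A3,indXpart,36,360,0.003542,0.000010,0.577
A3,indXreflection,45,450,0.007671,0.000017,6.198
A3,symmetricError,45,450,0.001457,0.000003,NA
A3,asymmetricError,45,450,0.001238,0.000003,NA
A3,totalError,45,900,0.002695,0.000003,NA
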