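scheme,region_label,region_order,group,n,mean,sd
rings,R1,1,control,25,32.252,5.487
rings,R2,2,control,25,14.928,3.734
rings,R3,3,control,25,9.448,2.698
rings,R4,4,control,25,5.840,1.941
rings,R5,5,control,25,4.372,1.120
rings,R1,1,case,20,21.515,5.402
rings,R2,2,case,20,9.63,3.587
rings,R3,3,case,20,7.02,2.233
rings,R4,4,case,20,4.31,1.694
rings,R5,5,case,20,3.19,0.865
sectors,S1,1,control,25,32.252,5.487
sectors,ST,2,control,25,7.208,1.598
sectors,SN,3,control,25,6.868,1.211
sectors,IN,4,control,25,6.888,1.270
sectors,IT,5,control,25,7.036,0.962
sectors,S1,1,case,20,21.515,5.402
sectors,ST,2,case,20,5.448,1.190
sectors,SN,3,case,20,5.481,1.458
sectors,IN,4,case,20,5.586,1.128
sectors,IT,5,case,20,5.676,1.342
etdrs,C,1,control,25,32.252,5.487
etdrs,T 5-10,2,control,25,19.972,3.568
etdrs,S 5-10,3,control,25,18.144,3.470
etdrs,N 5-10,4,control,25,19.468,5.565
etdrs,I 5-10,5,control,25,16.328,4.038
etdrs,T 10-20,6,control,25,8.156,1.467
etdrs,S 10-20,7,control,25,6.644,1.104
etdrs,N 10-20,8,control,25,7.096,1.064
etdrs,I 10-20,9,control,25,6.528,1.161
etdrs,C,1,case,20,21.515,5.402
etdrs,T 5-10,2,case,20,14.195,5.546
etdrs,S 5-10,3,case,20,14.805,4.888
etdrs,N 5-10,4,case,20,14.962,5.365
etdrs,I 5-10,5,case,20,12.752,4.614
etdrs,T 10-20,6,case,20,6.357,1.260
etdrs,S 10-20,7,case,20,5.690,1.099
etdrs,N 10-20,8,case,20,5.657,1.099
etdrs,I 10-20,9,case,20,5.119,1.171
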