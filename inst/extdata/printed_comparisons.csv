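table,comparison,scheme,group,region_a,region_b,printed_f
1,between,rings,NA,R1,NA,43.13
1,between,rings,NA,R2,NA,23.16
1,between,rings,NA,R3,NA,10.45
1,between,rings,NA,R4,NA,7.72
1,between,rings,NA,R5,NA,15.06
3,between,sectors,NA,S1,NA,43.13
3,between,sectors,NA,ST,NA,16.78
3,between,sectors,NA,SN,NA,12.16
3,between,sectors,NA,IN,NA,12.88
3,between,sectors,NA,IT,NA,15.66
5,between,etdrs,NA,C,NA,43.13
5,between,etdrs,NA,T 5-10,NA,17.92
5,between,etdrs,NA,S 5-10,NA,7.17
5,between,etdrs,NA,N 5-10,NA,7.85
5,between,etdrs,NA,I 5-10,NA,7.68
5,between,etdrs,NA,T 10-20,NA,18.9
5,between,etdrs,NA,S 10-20,NA,8.33
5,between,etdrs,NA,N 10-20,NA,19.74
5,between,etdrs,NA,I 10-20,NA,16.24
2,within,rings,control,R1,R2,170.33
2,within,rings,control,R1,R3,346.52
2,within,rings,control,R1,R4,514.83
2,within,rings,control,R1,R5,619.62
2,within,rings,control,R2,R3,35.38
2,within,rings,control,R2,R4,116.59
2,within,rings,control,R2,R5,183.31
2,within,rings,control,R3,R4,18.70
2,within,rings,control,R3,R5,51.16
2,within,rings,control,R4,R5,10.83
2,within,rings,case,R1,R2,67.19
2,within,rings,case,R1,R3,122.98
2,within,rings,case,R1,R4,184.71
2,within,rings,case,R1,R5,224.40
2,within,rings,case,R2,R3,7.63
2,within,rings,case,R2,R4,5.97
2,within,rings,case,R2,R5,60.92
2,within,rings,case,R3,R4,29.46
2,within,rings,case,R3,R5,75.48
2,within,rings,case,R4,R5,10.73
4,within,sectors,control,ST,SN,0.72
4,within,sectors,control,ST,IN,0.21
4,within,sectors,control,ST,IT,0.61
4,within,sectors,control,SN,IN,0.29
4,within,sectors,control,SN,IT,0.00
4,within,sectors,control,IN,IT,0.22
4,within,sectors,case,ST,SN,0.01
4,within,sectors,case,ST,IN,0.32
4,within,sectors,case,ST,IT,0.14
4,within,sectors,case,SN,IN,1.34
4,within,sectors,case,SN,IT,0.06
4,within,sectors,case,IN,IT,0.05
6,within,etdrs,control,S 5-10,T 5-10,3.37
6,within,etdrs,control,S 5-10,I 5-10,2.91
6,within,etdrs,control,S 5-10,N 5-10,1.02
6,within,etdrs,control,T 5-10,I 5-10,11.43
6,within,etdrs,control,T 5-10,N 5-10,3.37
6,within,etdrs,control,I 5-10,N 5-10,5.21
6,within,etdrs,case,S 5-10,T 5-10,0.14
6,within,etdrs,case,S 5-10,I 5-10,1.87
6,within,etdrs,case,S 5-10,N 5-10,0.01
6,within,etdrs,case,T 5-10,I 5-10,0.80
6,within,etdrs,case,T 5-10,N 5-10,0.20
6,within,etdrs,case,I 5-10,N 5-10,1.95
6,within,etdrs,control,S 10-20,T 10-20,16.95
6,within,etdrs,control,S 10-20,I 10-20,0.13
6,within,etdrs,control,S 10-20,N 10-20,3.25
6,within,etdrs,control,T 10-20,I 10-20,18.93
6,within,etdrs,control,T 10-20,N 10-20,8.55
6,within,etdrs,control,I 10-20,N 10-20,3.25
6,within,etdrs,case,S 10-20,T 10-20,3.18
6,within,etdrs,case,S 10-20,I 10-20,2.53
6,within,etdrs,case,S 10-20,N 10-20,0.01
6,within,etdrs,case,T 10-20,I 10-20,10.36
6,within,etdrs,case,T 10-20,N 10-20,3.51
6,within,etdrs,case,I 10-20,N 10-20,2.24
6,eccentricity,etdrs,control,S 10-20,S 5-10,249.35
6,eccentricity,etdrs,control,T 10-20,T 5-10,234.53
6,eccentricity,etdrs,control,I 10-20,I 5-10,136.01
6,eccentricity,etdrs,control,N 10-20,N 5-10,119.21
6,eccentricity,etdrs,case,S 10-20,S 5-10,66.20
6,eccentricity,etdrs,case,T 10-20,T 5-10,37.99
6,eccentricity,etdrs,case,I 10-20,I 5-10,51.42
6,eccentricity,etdrs,case,N 10-20,N 5-10,57.74
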