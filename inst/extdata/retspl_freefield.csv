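frequency_hz,retspl_dbspl
125,22.1
160,17.9
200,14.4
250,11.4
315,8.6
400,6.2
500,4.4
630,3.0
750,2.4
800,2.2
1000,2.4
1250,3.5
1500,2.4
1600,1.7
2000,-1.3
2500,-4.2
3000,-5.8
3150,-6.0
4000,-5.4
5000,-1.5
6000,4.3
6300,6.0
8000,12.6
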