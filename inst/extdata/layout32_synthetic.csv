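id,label,ap_mm,ml_mm,hemisphere,region_class
0,M2-L2,2,-1.95,left,rostral
1,M2-L1,2,-0.65,left,rostral
2,M2-R1,2,0.65,right,rostral
3,M2-R2,2,1.95,right,rostral
4,M1-L2,0.094048,-1.95,left,rostral
5,M1-L1,0.094048,-0.65,left,rostral
6,M1-R1,0.094048,0.65,right,rostral
7,M1-R2,0.094048,1.95,right,rostral
8,S1FL-L2,-1.811904,-1.95,left,rostral
9,S1FL-L1,-1.811904,-0.65,left,rostral
10,S1FL-R1,-1.811904,0.65,right,rostral
11,S1FL-R2,-1.811904,1.95,right,rostral
12,S1BF-L2,-3.717856,-1.95,left,middle
13,S1BF-L1,-3.717856,-0.65,left,middle
14,S1BF-R1,-3.717856,0.65,right,middle
15,S1BF-R2,-3.717856,1.95,right,middle
16,S1Tr-L2,-5.623808,-1.95,left,middle
17,S1Tr-L1,-5.623808,-0.65,left,middle
18,S1Tr-R1,-5.623808,0.65,right,middle
19,S1Tr-R2,-5.623808,1.95,right,middle
20,PtA-L2,-7.52976,-1.95,left,caudal
21,PtA-L1,-7.52976,-0.65,left,caudal
22,PtA-R1,-7.52976,0.65,right,caudal
23,PtA-R2,-7.52976,1.95,right,caudal
24,V2-L2,-9.435712,-1.95,left,caudal
25,V2-L1,-9.435712,-0.65,left,caudal
26,V2-R1,-9.435712,0.65,right,caudal
27,V2-R2,-9.435712,1.95,right,caudal
28,V1-L2,-11.341664,-1.95,left,caudal
29,V1-L1,-11.341664,-0.65,left,caudal
30,V1-R1,-11.341664,0.65,right,caudal
31,V1-R2,-11.341664,1.95,right,caudal
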