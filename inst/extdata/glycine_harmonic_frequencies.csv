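# Published benchmark harmonic frequencies (cm^-1) for the glycine global
# minimum: ab initio (B3LYP/aug-cc-pVDZ) values alongside those of two
# third-order PIP surfaces (full-molecule and three-fragment) fitted to the
# same level of theory. 24 vibrational modes, matched order.
mode,ab_initio,full_order3,threefrag_order3
1,61.7,100.1,34.7
2,211.6,231.2,209.9
3,256.0,260.6,238.6
4,461.3,466.1,459.3
5,512.3,526.0,531.6
6,630.2,631.6,574.2
7,648.4,647.7,641.6
8,816.9,820.6,810.7
9,908.3,906.5,898.5
10,912.2,918.4,942.2
11,1122.6,1124.4,1129.3
12,1160.9,1161.0,1148.4
13,1176.2,1178.2,1158.1
14,1297.8,1291.0,1288.2
15,1371.8,1370.1,1357.7
16,1385.0,1379.0,1374.2
17,1437.3,1444.4,1443.7
18,1656.6,1664.2,1674.6
19,1803.6,1793.3,1787.7
20,3045.9,3037.3,3017.7
21,3083.7,3041.3,3058.7
22,3493.8,3466.4,3457.3
23,3567.1,3547.5,3540.6
24,3735.2,3704.1,3719.5
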