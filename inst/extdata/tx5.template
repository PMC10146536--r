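n_eo 5
resname TX5
[atoms]
CM1 CH3 C 15.0350 0.2000 TAIL_C C1 -0.120
CM2 CH3 C 15.0350 0.2000 TAIL_C . -0.120
CM3 CH3 C 15.0350 0.2000 TAIL_C . -0.120
CQ C C 12.0110 0.1700 QUATERNARY_C C2 0.000
CB CH2 C 14.0270 0.2000 TAIL_C C3 0.140
CG C C 12.0110 0.1700 TAIL_C C4 0.280
CM4 CH3 C 15.0350 0.2000 TAIL_C . 0.240
CM5 CH3 C 15.0350 0.2000 TAIL_C . 0.240
CR1 CR1 C 13.0190 0.1900 RING_C CR 0.390
CR2 CR1 C 13.0190 0.1900 RING_C . 0.460
CR3 CR1 C 13.0190 0.1900 RING_C . 0.600
CR4 CR1 C 13.0190 0.1900 RING_C . 0.670
CR5 CR1 C 13.0190 0.1900 RING_C . 0.600
CR6 CR1 C 13.0190 0.1900 RING_C . 0.460
O1 OA O 15.9990 0.1520 EO_O O1 0.810
CA1 CH2 C 14.0270 0.2000 EO_C . 0.890
CB1 CH2 C 14.0270 0.2000 EO_C . 0.970
O2 OA O 15.9990 0.1520 EO_O O2 1.050
CA2 CH2 C 14.0270 0.2000 EO_C . 1.130
CB2 CH2 C 14.0270 0.2000 EO_C . 1.210
O3 OA O 15.9990 0.1520 EO_O O3 1.290
CA3 CH2 C 14.0270 0.2000 EO_C . 1.370
CB3 CH2 C 14.0270 0.2000 EO_C . 1.450
O4 OA O 15.9990 0.1520 EO_O O4 1.530
CA4 CH2 C 14.0270 0.2000 EO_C . 1.610
CB4 CH2 C 14.0270 0.2000 EO_C . 1.690
O5 OA O 15.9990 0.1520 EO_O O5 1.770
CA5 CH2 C 14.0270 0.2000 EO_C . 1.850
CB5 CH2 C 14.0270 0.2000 EO_C . 1.930
OH OA O 15.9990 0.1520 HYDROXYL_O OH 2.010
HO H H 1.0080 0.1200 HYDROXYL_H HO 2.090
[bonds]
1 4
2 4
3 4
4 5
5 6
6 7
6 8
6 9
9 10
10 11
11 12
12 13
13 14
14 9
12 15
15 16
16 17
17 18
18 19
19 20
20 21
21 22
22 23
23 24
24 25
25 26
26 27
27 28
28 29
29 30
30 31
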