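case_id,fold_group,areas,preds,printed_total
1,1,1,1,1
2,1,0.10;0.28;0.16,1;1;1,0.54
3,1,0.44;0.56;0.40,1;1;1,1.40
4,1,0.17;0.20,1;1,0.37
5,1,0.34;0.23,1;1,0.57
6,1,0.09;0.17;0.16;0.02;0.04,1;1;1;1;1,0.47
7,1,0.27;0.19;0.19,1;1;1,0.66
8,1,0.24;0.40;0.38,1;1;1,1.02
9,1,0.25;0.59,-1;-1,-0.84
10,1,0.79;0.28,1;1,1.06
11,1,0.37;0.57;0.44,-1;-1;-1,-1.38
12,1,0.31;0.37;0.63,1;1;1,1.30
13,1,0.54,1,0.54
14,1,0.36;0.84,1;-1,-0.48
15,1,0.78;0.78,1;1,1.56
16,1,0.56;0.67;0.50,1;1;1,1.74
17,1,0.38;0.10;0.23;0.28,1;1;1;1,0.99
18,1,0.44;0.41,1;1,0.85
19,1,0.25;0.12,1;1,0.38
20,2,0.28;0.04;0.19;0.08,1;-1;1;1,0.51
21,2,0.59;0.74,1;1,1.33
22,2,0.30;0.08;0.13,-1;-1;-1,-0.51
23,2,0.51;0.18;0.39;0.11,-1;-1;-1;-1,-1.19
24,2,0.42;0.01;0.47,1;-1;-1,-0.06
25,2,0.17;0.08;0.05;0.08,1;1;1;1,0.38
26,2,0.27;0.07;0.36,-1;1;-1,-0.55
27,2,0.13,1,0.13
28,2,0.14;0.21,1;1,0.35
29,2,0.08;0.04;0.22,1;1;1,0.35
30,2,0.37;0.25;0.19,1;1;1,0.81
31,2,0.37;0.27,1;1,0.64
32,2,0.66,-1,-0.66
33,2,0.21;0.33;0.24;0.24,1;1;1;1,1.03
34,2,0.85;0.96,1;1,1.81
35,2,0.07;0.02;0.01;0.01;0.07;0.01;0.01,-1;1;1;1;1;1;1,0.07
36,2,0.54;0.40;0.52,-1;1;1,0.39
37,2,0.40;0.14;0.13,-1;-1;-1,-0.66
38,2,0.37;0.20;0.37,-1;-1;-1,-0.94
39,3,0.28;0.23;0.34;0.33,-1;-1;-1;-1,-1.18
40,3,0.26;0.31,-1;-1,-0.57
41,3,0.58;0.41;0.36,-1;-1;-1,-1.34
42,3,0.38;0.30,-1;1,-0.07
43,3,0.19,1,0.19
44,3,0.30;0.23;0.32;0.27,-1;-1;-1;-1,-1.12
45,3,0.16;0.12;0.14;0.08,1;1;1;1,0.49
46,3,0.53;0.26;0.06;0.54;0.47,1;1;1;1;1,1.87
47,3,0.28;0.23;0.24,1;1;1,0.75
48,3,0.58,-1,-0.58
49,3,0.46;0.52,1;1,0.99
50,3,0.48;0.32;0.23;0.21;0.23;0.20,-1;1;-1;-1;-1;1,-0.64
51,3,0.42;0.05;0.36,1;1;1,0.83
52,3,0.47;0.16;0.05;0.46,-1;-1;-1;-1,-1.14
53,3,0.43;0.07;0.43;0.03;0.30,-1;1;1;1;-1,-0.20
54,3,0.59;0.34;0.47,-1;-1;-1,-1.40
55,3,0.29;0.32;0.48;0.42,-1;-1;-1;-1,-1.50
56,3,0.17;0.40;0.04;0.28,-1;-1;-1;-1,-0.90
57,3,0.38;0.18;0.25;0.28;0.08;0.01;0.04,-1;-1;-1;-1;-1;1;-1,-1.21
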