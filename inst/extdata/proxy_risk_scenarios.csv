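scenario_id,v_low_pct,v_high_pct
1,30,70
2,40,75
3,25,30
4,50,50
5,100,100
6,150,150
7,65,55
8,75,60
9,125,100
10,150,120
11,75,55
12,150,110
13,55,40
14,95,65
15,75,50
16,90,60
17,150,100
18,125,80
19,65,40
20,25,15
21,75,45
22,125,75
23,150,90
24,70,40
25,125,70
26,75,40
27,150,80
28,70,35
29,80,40
30,85,40
31,75,35
32,80,35
33,70,30
34,50,20
35,75,30
36,95,35
37,85,30
38,30,10
39,75,25
40,150,50
41,125,40
42,150,25
43,125,20
44,90,10
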