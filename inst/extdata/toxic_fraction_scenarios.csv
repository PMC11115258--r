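scenario_id,v_low_pct,v_high_pct
1,30,70
2,40,75
3,25,30
4,50,50
5,100,100
6,65,55
7,75,60
8,75,55
9,55,40
10,95,65
11,75,50
12,90,60
13,65,40
14,25,15
15,75,45
16,70,40
17,75,40
18,70,35
19,80,40
20,85,40
21,75,35
22,80,35
23,70,30
24,50,20
25,75,30
26,95,35
27,85,30
28,30,10
29,75,25
30,90,10
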