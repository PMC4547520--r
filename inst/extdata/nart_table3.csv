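test_order,item,h_i,pct_correct
4,AISLE,0.570,99.1
10,DEBT,0.592,99.0
6,PSALM,0.409,98.5
18,HEIR,0.508,98.0
3,DEPOT,0.391,97.4
9,NAUSEA,0.483,97.4
5,BOUQUET,0.455,96.9
14,NAIVE,0.502,93.0
17,THYME,0.484,86.7
24,GIST,0.534,83.1
16,GAOLED,0.462,76.8
30,CELLIST,0.526,72.9
29,QUADRUPED,0.519,69.5
36,ABSTEMIOUS,0.541,67.6
41,GAUCHE,0.502,63.2
40,AVER,0.476,58.4
37,DETENTE,0.550,55.0
38,IDYLL,0.523,47.5
44,BEATIFY,0.561,37.3
43,LEVIATHAN,0.622,35.7
47,DEMESNE,0.701,22.0
46,SIDEREAL,0.606,17.2
49,LABILE,0.581,14.1
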