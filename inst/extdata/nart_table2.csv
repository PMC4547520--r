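test_order,item,pct_correct
2,ACHE,99.3
4,AISLE,99.1
10,DEBT,99.0
1,CHORD,99.0
6,PSALM,98.5
18,HEIR,98.0
3,DEPOT,97.4
9,NAUSEA,97.4
5,BOUQUET,96.9
14,NAIVE,93.0
23,PROCREATE,93.0
8,DENY,91.6
25,GOUGE,90.6
35,PLACEBO,89.9
20,ASSIGNATE,89.8
11,COURTEOUS,89.4
22,SUBTLE,89.1
12,RAREFY,88.6
17,THYME,86.7
13,EQUIVOCAL,85.8
27,SIMILE,85.7
7,CAPON,85.3
26,SUPERFLUOUS,84.7
21,HIATUS,84.7
24,GIST,83.1
32,ZEALOT,80.6
28,BANAL,79.4
15,CATACOMB,78.4
16,GAOLED,76.8
31,FACADE,75.1
30,CELLIST,72.9
42,TOPIARY,72.6
29,QUADRUPED,69.5
36,ABSTEMIOUS,67.6
41,GAUCHE,63.2
40,AVER,58.4
37,DETENTE,55.0
38,IDYLL,47.5
19,RADIX,44.1
34,AEON,42.4
39,PUERPERAL,40.7
44,BEATIFY,37.3
43,LEVIATHAN,35.7
45,PRELATE,31.7
48,SYNCOPE,28.8
47,DEMESNE,22.0
50,CAMPANILE,17.4
46,SIDEREAL,17.2
49,LABILE,14.1
33,DRACHM,13.8
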