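scorer,synthmodel,synthmodel,synthmodel
bodyparts,toe,toe,toe
coords,x,y,likelihood
0,300.685,230.600,0.99
1,304.944,230.358,0.99
2,310.577,228.843,0.99
3,315.767,229.456,0.99
4,320.539,227.073,0.99
5,324.947,226.034,0.99
6,330.145,224.059,0.99
7,333.409,222.233,0.99
8,338.166,220.168,0.99
9,340.419,217.693,0.99
10,343.954,214.987,0.99
11,346.821,212.256,0.99
12,346.858,209.028,0.99
13,348.768,205.985,0.99
14,349.659,202.305,0.99
15,350.318,199.809,0.99
16,349.584,196.608,0.99
17,347.579,195.114,0.99
18,346.333,190.048,0.99
19,346.337,187.867,0.99
20,343.148,184.253,0.99
21,339.560,181.631,0.99
22,337.071,179.988,0.99
23,334.064,177.207,0.99
24,330.337,175.729,0.99
25,324.785,173.805,0.99
26,320.208,172.287,0.99
27,314.569,170.456,0.99
28,310.626,170.043,0.99
29,304.906,170.254,0.99
30,300.228,170.284,0.20
31,295.126,169.918,0.20
32,290.122,170.656,0.20
33,284.245,172.030,0.99
34,279.916,173.314,0.99
35,274.141,173.471,0.99
36,270.219,175.671,0.99
37,266.118,178.306,0.99
38,261.636,179.691,0.99
39,259.567,182.340,0.99
40,256.802,184.957,0.99
41,254.142,187.354,0.99
42,252.826,190.507,0.99
43,250.729,193.748,0.99
44,249.590,196.657,0.99
45,250.216,200.557,0.99
46,249.868,202.895,0.99
47,251.815,206.021,0.99
48,252.231,209.619,0.99
49,254.651,211.674,0.99
50,256.860,214.980,0.99
51,259.157,216.858,0.99
52,263.631,220.658,0.99
53,266.865,222.158,0.99
54,270.656,224.037,0.99
55,275.138,225.362,0.99
56,280.003,227.402,0.99
57,284.594,228.132,0.99
58,288.108,229.078,0.99
59,294.916,230.479,0.99
60,299.816,229.912,0.10
61,305.319,229.300,0.10
62,310.686,229.426,0.10
63,316.151,228.350,0.10
64,319.973,227.701,0.10
65,325.651,226.697,0.10
66,329.557,223.774,0.10
67,333.976,222.522,0.10
68,337.618,220.116,0.10
69,340.811,218.081,0.10
70,342.780,214.885,0.10
71,345.632,212.620,0.10
72,347.865,208.398,0.10
73,348.431,207.082,0.10
74,349.455,203.568,0.10
75,350.290,199.925,0.10
76,350.110,196.140,0.99
77,349.139,194.084,0.99
78,347.110,190.971,0.99
79,345.127,187.795,0.99
80,344.058,185.076,0.99
81,340.580,182.074,0.99
82,337.201,180.110,0.99
83,333.396,177.853,0.99
84,328.792,175.590,0.99
85,325.306,173.351,0.99
86,320.228,172.944,0.99
87,315.359,171.745,0.99
88,310.862,170.237,0.99
89,305.637,169.367,0.99
90,300.696,170.102,0.99
91,294.535,169.992,0.99
92,289.930,170.782,0.99
93,285.245,170.821,0.99
94,279.108,172.114,0.99
95,274.570,174.562,0.99
96,270.045,175.931,0.99
97,265.814,177.999,0.99
98,262.883,180.834,0.99
99,259.876,182.431,0.99
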