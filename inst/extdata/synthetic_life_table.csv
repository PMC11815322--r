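age,sex,qx
45,male,0.00204041
46,male,0.00223256
47,male,0.00244281
48,male,0.00267286
49,male,0.00292458
50,male,0.00320000
51,male,0.00350136
52,male,0.00383110
53,male,0.00419189
54,male,0.00458665
55,male,0.00501860
56,male,0.00549122
57,male,0.00600835
58,male,0.00657419
59,male,0.00719331
60,male,0.00787073
61,male,0.00861195
62,male,0.00942297
63,male,0.01031038
64,male,0.01128135
65,male,0.01234376
66,male,0.01350623
67,male,0.01477817
68,male,0.01616989
69,male,0.01769268
70,male,0.01935887
71,male,0.02118198
72,male,0.02317678
73,male,0.02535943
74,male,0.02774764
75,male,0.03036075
76,male,0.03321996
77,male,0.03634842
78,male,0.03977151
79,male,0.04351696
80,male,0.04761514
81,male,0.05209926
82,male,0.05700567
83,male,0.06237414
84,male,0.06824818
85,male,0.07467541
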