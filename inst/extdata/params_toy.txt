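# wavefold nearest-neighbor thermodynamic parameter file
# energies in kcal/mol, two decimals
MISC
terminal_au 0.50
min_hairpin_unpaired 3
loop_max 30
extrapolation_coeff 1.08
rt 0.62
asymmetry_coeff 0.50
asymmetry_max 3.00
allowed_pairs AU UA CG GC GU UG
MULTILOOP
offset 3.40
branch 0.40
unpaired 0.40
STACK
AU AU -1.10
AU UA -1.10
AU CG -1.60
AU GC -1.60
AU GU -0.90
AU UG -0.90
UA AU -1.10
UA UA -1.10
UA CG -1.60
UA GC -1.60
UA GU -0.90
UA UG -0.90
CG AU -1.60
CG UA -1.60
CG CG -2.10
CG GC -2.10
CG GU -1.40
CG UG -1.40
GC AU -1.60
GC UA -1.60
GC CG -2.10
GC GC -2.10
GC GU -1.40
GC UG -1.40
GU AU -0.90
GU UA -0.90
GU CG -1.40
GU GC -1.40
GU GU -0.70
GU UG -0.70
UG AU -0.90
UG UA -0.90
UG CG -1.40
UG GC -1.40
UG GU -0.70
UG UG -0.70
HAIRPIN_INIT
1 5.00
2 5.00
3 4.60
4 4.65
5 4.70
6 4.75
7 4.80
8 4.85
9 4.90
10 4.95
11 5.00
12 5.05
13 5.10
14 5.15
15 5.20
16 5.25
17 5.30
18 5.35
19 5.40
20 5.45
21 5.50
22 5.55
23 5.60
24 5.65
25 5.70
26 5.75
27 5.80
28 5.85
29 5.90
30 5.95
BULGE_INIT
1 3.60
2 3.65
3 3.70
4 3.75
5 3.80
6 3.85
7 3.90
8 3.95
9 4.00
10 4.05
11 4.10
12 4.15
13 4.20
14 4.25
15 4.30
16 4.35
17 4.40
18 4.45
19 4.50
20 4.55
21 4.60
22 4.65
23 4.70
24 4.75
25 4.80
26 4.85
27 4.90
28 4.95
29 5.00
30 5.05
INTERNAL_INIT
1 1.70
2 1.70
3 1.75
4 1.80
5 1.85
6 1.90
7 1.95
8 2.00
9 2.05
10 2.10
11 2.15
12 2.20
13 2.25
14 2.30
15 2.35
16 2.40
17 2.45
18 2.50
19 2.55
20 2.60
21 2.65
22 2.70
23 2.75
24 2.80
25 2.85
26 2.90
27 2.95
28 3.00
29 3.05
30 3.10
TMISMATCH_H
AU A A -0.15
AU A C -0.45
AU A G -0.15
AU A U -0.45
AU C A -0.30
AU C C -0.60
AU C G -0.30
AU C U -0.60
AU G A -0.45
AU G C -0.15
AU G G -0.45
AU G U -0.15
AU U A -0.60
AU U C -0.30
AU U G -0.60
AU U U -0.30
UA A A -0.30
UA A C -0.60
UA A G -0.30
UA A U -0.60
UA C A -0.45
UA C C -0.15
UA C G -0.45
UA C U -0.15
UA G A -0.60
UA G C -0.30
UA G G -0.60
UA G U -0.30
UA U A -0.15
UA U C -0.45
UA U G -0.15
UA U U -0.45
CG A A -0.45
CG A C -0.15
CG A G -0.45
CG A U -0.15
CG C A -0.60
CG C C -0.30
CG C G -0.60
CG C U -0.30
CG G A -0.15
CG G C -0.45
CG G G -0.15
CG G U -0.45
CG U A -0.30
CG U C -0.60
CG U G -0.30
CG U U -0.60
GC A A -0.60
GC A C -0.30
GC A G -0.60
GC A U -0.30
GC C A -0.15
GC C C -0.45
GC C G -0.15
GC C U -0.45
GC G A -0.30
GC G C -0.60
GC G G -0.30
GC G U -0.60
GC U A -0.45
GC U C -0.15
GC U G -0.45
GC U U -0.15
GU A A -0.15
GU A C -0.45
GU A G -0.15
GU A U -0.45
GU C A -0.30
GU C C -0.60
GU C G -0.30
GU C U -0.60
GU G A -0.45
GU G C -0.15
GU G G -0.45
GU G U -0.15
GU U A -0.60
GU U C -0.30
GU U G -0.60
GU U U -0.30
UG A A -0.30
UG A C -0.60
UG A G -0.30
UG A U -0.60
UG C A -0.45
UG C C -0.15
UG C G -0.45
UG C U -0.15
UG G A -0.60
UG G C -0.30
UG G G -0.60
UG G U -0.30
UG U A -0.15
UG U C -0.45
UG U G -0.15
UG U U -0.45
TMISMATCH_I
AU A A -0.10
AU A C -0.30
AU A G -0.10
AU A U -0.30
AU C A -0.20
AU C C -0.40
AU C G -0.20
AU C U -0.40
AU G A -0.30
AU G C -0.10
AU G G -0.30
AU G U -0.10
AU U A -0.40
AU U C -0.20
AU U G -0.40
AU U U -0.20
UA A A -0.20
UA A C -0.40
UA A G -0.20
UA A U -0.40
UA C A -0.30
UA C C -0.10
UA C G -0.30
UA C U -0.10
UA G A -0.40
UA G C -0.20
UA G G -0.40
UA G U -0.20
UA U A -0.10
UA U C -0.30
UA U G -0.10
UA U U -0.30
CG A A -0.30
CG A C -0.10
CG A G -0.30
CG A U -0.10
CG C A -0.40
CG C C -0.20
CG C G -0.40
CG C U -0.20
CG G A -0.10
CG G C -0.30
CG G G -0.10
CG G U -0.30
CG U A -0.20
CG U C -0.40
CG U G -0.20
CG U U -0.40
GC A A -0.40
GC A C -0.20
GC A G -0.40
GC A U -0.20
GC C A -0.10
GC C C -0.30
GC C G -0.10
GC C U -0.30
GC G A -0.20
GC G C -0.40
GC G G -0.20
GC G U -0.40
GC U A -0.30
GC U C -0.10
GC U G -0.30
GC U U -0.10
GU A A -0.10
GU A C -0.30
GU A G -0.10
GU A U -0.30
GU C A -0.20
GU C C -0.40
GU C G -0.20
GU C U -0.40
GU G A -0.30
GU G C -0.10
GU G G -0.30
GU G U -0.10
GU U A -0.40
GU U C -0.20
GU U G -0.40
GU U U -0.20
UG A A -0.20
UG A C -0.40
UG A G -0.20
UG A U -0.40
UG C A -0.30
UG C C -0.10
UG C G -0.30
UG C U -0.10
UG G A -0.40
UG G C -0.20
UG G G -0.40
UG G U -0.20
UG U A -0.10
UG U C -0.30
UG U G -0.10
UG U U -0.30
DANGLE5
AU A -0.30
AU C -0.10
AU G -0.20
AU U -0.30
UA A -0.10
UA C -0.20
UA G -0.30
UA U -0.10
CG A -0.20
CG C -0.30
CG G -0.10
CG U -0.20
GC A -0.30
GC C -0.10
GC G -0.20
GC U -0.30
GU A -0.10
GU C -0.20
GU G -0.30
GU U -0.10
UG A -0.20
UG C -0.30
UG G -0.10
UG U -0.20
DANGLE3
AU A -0.10
AU C -0.30
AU G -0.20
AU U -0.10
UA A -0.20
UA C -0.10
UA G -0.30
UA U -0.20
CG A -0.30
CG C -0.20
CG G -0.10
CG U -0.30
GC A -0.10
GC C -0.30
GC G -0.20
GC U -0.10
GU A -0.20
GU C -0.10
GU G -0.30
GU U -0.20
UG A -0.30
UG C -0.20
UG G -0.10
UG U -0.30
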