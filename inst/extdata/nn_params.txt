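# Simplified nearest-neighbor free-energy parameters (kcal/mol, 37 C).
# Stacks: outer pair then inner pair (5'->3' on the outer i strand),
# pair codes over {AU, UA, GC, CG, GU, UG}. Loop penalties are tabulated
# by size with a logarithmic extrapolation term 'ext':
#   dG(size) = dG(size_max) + ext * ln(size / size_max)   for size > size_max.
[stack]
AU AU -0.9
AU UA -1.1
AU GC -2.1
AU CG -2.2
AU GU -0.6
AU UG -1.4
UA AU -1.3
UA UA -0.9
UA GC -2.4
UA CG -2.1
UA GU -1.0
UA UG -1.3
GC AU -2.2
GC UA -2.4
GC GC -3.3
GC CG -3.4
GC GU -1.5
GC UG -2.5
CG AU -2.1
CG UA -2.1
CG GC -2.4
CG CG -3.3
CG GU -1.4
CG UG -2.1
GU AU -0.8
GU UA -1.0
GU GC -1.4
GU CG -2.5
GU GU -0.5
GU UG -0.4
UG AU -0.6
UG UA -0.8
UG GC -1.5
UG CG -1.4
UG GU -0.2
UG UG -0.5
[hairpin]
3 5.4
4 5.6
5 5.7
6 5.4
7 6.0
8 5.5
9 6.4
ext 1.08
[internal]
1 3.8
2 2.8
3 3.2
4 3.6
5 4.0
6 4.4
7 4.6
8 4.7
9 4.8
ext 1.08
[multibranch]
offset 3.4
branch 0.4
unpaired 0.1
[general]
min_hairpin 3
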