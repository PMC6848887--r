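# SWC export
1 1 0.000000 0.000000 0.000000 9.150000 -1
2 3 -50.000000 86.602540 0.000000 0.875000 1
3 3 -100.000000 173.205081 0.000000 0.625000 2
4 3 -150.000000 259.807621 0.000000 0.375000 3
5 3 -50.000000 -86.602540 0.000000 0.875000 1
6 3 -100.000000 -173.205081 0.000000 0.625000 5
7 3 -150.000000 -259.807621 0.000000 0.375000 6
8 3 100.000000 -0.000000 0.000000 0.875000 1
9 3 200.000000 -0.000000 0.000000 0.625000 8
10 3 300.000000 -0.000000 0.000000 0.375000 9
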