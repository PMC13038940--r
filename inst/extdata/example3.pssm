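
Last position-specific scoring matrix computed, weighted observed percentages rounded down, information per position, and relative weight of gapless real matches to pseudocounts
             A   R   N   D   C   Q   E   G   H   I   L   K   M   F   P   S   T   W   Y   V   A   R   N   D   C   Q   E   G   H   I   L   K   M   F   P   S   T   W   Y   V
    1 M     -1  -2  -3  -4   0  -1  -2  -3  -2   1   2   0   6   0  -3  -2  -1  -2  -1   1    0   0   0   0   0   0   0   0   0   0   0   0 100   0   0   0   0   0   0   0  0.80 0.10
    2 K     -1   2   0  -1  -4   1   1  -2  -1  -3  -3   5  -2  -4  -1   0  -1  -3  -2  -3    0   0   0   0   0   0   0   0   0   0   0  90   0   0   0   5   0   0   0   5  0.62 0.12
    3 A      4  -2  -2  -2   0  -1  -1   0  -2  -2  -2  -1  -1  -3  -1   1   0  -3  -2   0   80   0   0   0   0   0   0   5   0   0   0   0   0   0   0  10   5   0   0   0  0.45 0.09

                      K         Lambda
Standard Ungapped     0.1347    0.3179
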