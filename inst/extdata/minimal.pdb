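ATOM      1  N   ALA A   1      11.104   6.134  -6.504  1.00  0.00           N
ATOM      2  CA  ALA A   1      11.639   6.071  -5.147  1.00  0.00           C
ATOM      3  C   ALA A   1      10.697   6.745  -4.123  1.00  0.00           C
ATOM      4  O   ALA A   1       9.561   7.083  -4.470  1.00  0.00           O
ATOM      5  CB  ALA A   1      11.873   4.618  -4.712  1.00  0.00           C
END
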