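ATOM      1  CA  ALA A  10      11.104   6.134  -6.504  1.00  0.00 POC  1
ATOM      2  CA  GLY A  12       8.014   5.234  -4.104  1.00  0.00 POC  1
ATOM      3  CB  GLY A  12       8.514   5.834  -3.104  1.00  0.00 POC  1
ATOM      4  CA  LYS A  45       6.104   2.134  -1.504  1.00  0.00 POC  1
ATOM      5  CA  SER A  47       4.104   1.134   0.496  1.00  0.00 POC  1
ATOM      6  CA  TRP B   3      21.104  16.134   6.504  1.00  0.00 POC  2
ATOM      7  CA  PHE B   5      18.014  15.234   4.104  1.00  0.00 POC  2
ATOM      8  CA  ARG B   9      16.104  12.134   1.504  1.00  0.00 POC  2
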