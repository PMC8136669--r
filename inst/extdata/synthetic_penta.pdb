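ATOM      1  N   ALA A   1       0.000   0.000   0.000  1.00  0.00              
ATOM      2  CA  ALA A   1       1.458   0.000   0.000  1.00  0.00              
ATOM      3  C   ALA A   1       2.009   1.422   0.000  1.00  0.00              
ATOM      4  N   GLU A   2       1.478   2.280   0.864  1.00  0.00              
ATOM      5  CA  GLU A   2       1.930   3.663   0.948  1.00  0.00              
ATOM      6  C   GLU A   2       1.802   4.368  -0.398  1.00  0.00              
ATOM      7  N   LEU A   3       0.654   4.223  -1.052  1.00  0.00              
ATOM      8  CA  LEU A   3       0.425   4.853  -2.347  1.00  0.00              
ATOM      9  C   LEU A   3       1.484   4.432  -3.360  1.00  0.00              
ATOM     10  N   ALA A   4       1.764   3.136  -3.443  1.00  0.00              
ATOM     11  CA  ALA A   4       2.760   2.625  -4.377  1.00  0.00              
ATOM     12  C   ALA A   4       4.117   3.283  -4.152  1.00  0.00              
ATOM     13  N   MET A   5       4.554   3.360  -2.899  1.00  0.00              
ATOM     14  CA  MET A   5       5.838   3.969  -2.572  1.00  0.00              
ATOM     15  C   MET A   5       5.911   5.406  -3.077  1.00  0.00              
END   
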