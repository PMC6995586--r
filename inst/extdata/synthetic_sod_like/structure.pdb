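ATOM      1  CA  ASN A   1       2.300   0.000   0.000  1.00  0.00              
ATOM      2  CA  ILE A   2      -0.399   2.265   1.500  1.00  0.00              
ATOM      3  CA  GLU A   3      -2.161  -0.787   3.000  1.00  0.00              
ATOM      4  CA  CYS A   4       1.150  -1.992   4.500  1.00  0.00              
ATOM      5  CA  PHE A   5       1.762   1.478   6.000  1.00  0.00              
ATOM      6  CA  PRO A   6      -1.762   1.478   7.500  1.00  0.00              
ATOM      7  CA  HIS A   7      -1.150  -1.992   9.000  1.00  0.00              
ATOM      8  CA  HIS A   8       2.161  -0.787  10.500  1.00  0.00              
ATOM      9  CA  CYS A   9       0.399   2.265  12.000  1.00  0.00              
ATOM     10  CA  HIS A  10      -2.300   0.000  13.500  1.00  0.00              
ATOM     11  CA  GLN A  11       0.399  -2.265  15.000  1.00  0.00              
ATOM     12  CA  LYS A  12       2.161   0.787  16.500  1.00  0.00              
ATOM     13  CA  ALA A  13      -1.150   1.992  18.000  1.00  0.00              
ATOM     14  CA  TYR A  14      -1.762  -1.478  19.500  1.00  0.00              
ATOM     15  CA  TRP A  15       1.762  -1.478  21.000  1.00  0.00              
ATOM     16  CA  PRO A  16       1.150   1.992  22.500  1.00  0.00              
ATOM     17  CA  ILE A  17      -2.161   0.787  24.000  1.00  0.00              
ATOM     18  CA  GLN A  18      -0.399  -2.265  25.500  1.00  0.00              
ATOM     19  CA  GLU A  19       2.300  -0.000  27.000  1.00  0.00              
ATOM     20  CA  ASP A  20      -0.399   2.265  28.500  1.00  0.00              
ATOM     21  CA  GLN A  21      -2.161  -0.787  30.000  1.00  0.00              
ATOM     22  CA  ALA A  22       1.150  -1.992  31.500  1.00  0.00              
ATOM     23  CA  GLN A  23       1.762   1.478  33.000  1.00  0.00              
ATOM     24  CA  ILE A  24      -1.762   1.478  34.500  1.00  0.00              
ATOM     25  CA  LEU A  25      -1.150  -1.992  36.000  1.00  0.00              
ATOM     26  CA  TYR A  26       2.161  -0.787  37.500  1.00  0.00              
ATOM     27  CA  TYR A  27       0.399   2.265  39.000  1.00  0.00              
ATOM     28  CA  GLU A  28      -2.300  -0.000  40.500  1.00  0.00              
ATOM     29  CA  HIS A  29       0.399  -2.265  42.000  1.00  0.00              
ATOM     30  CA  TRP A  30       2.161   0.787  43.500  1.00  0.00              
END   
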