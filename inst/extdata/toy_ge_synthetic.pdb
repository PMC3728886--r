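HETATM    1  C1  XYL X   1      -1.500   0.000   0.000  1.00  0.00           C  
HETATM    2  O5  XYL X   1      -2.050   1.250   0.150  1.00  0.00           O  
HETATM    3  C2  XYL X   1      -2.200  -1.200   0.300  1.00  0.00           C  
HETATM    4  O2  XYL X   1      -3.350  -1.600   0.450  1.00  0.00           O  
HETATM    5  O1  ONP X   2      -4.000   0.050   0.000  1.00  0.00           O  
HETATM    6  C7  ONP X   2      -5.350   0.300   0.050  1.00  0.00           C  
HETATM    7  O7  ONP X   2      -6.050   1.350   0.200  1.00  0.00           O  
ATOM      8  OE1 GLU A  10       0.000   0.000   0.000  1.00  0.00           O  
ATOM      9  CD  GLU A  10       1.250   0.350   0.000  1.00  0.00           C  
ATOM     10  OE2 GLU A  10       1.900   1.350   0.100  1.00  0.00           O  
ATOM     11  CG  GLU A  10       2.100  -0.850  -0.100  1.00  0.00           C  
ATOM     12  N   ALA A  11      -1.977  -3.403   3.117  1.00  0.00           N  
ATOM     13  CA  ALA A  11      -3.091  -3.875   3.916  1.00  0.00           C  
ATOM     14  C   ALA A  11      -3.976  -4.819   3.117  1.00  0.00           C  
ATOM     15  O   ALA A  11      -4.849  -5.593   2.725  1.00  0.00           O  
ATOM     16  CB  ALA A  11      -3.914  -2.695   4.437  1.00  0.00           C  
ATOM     17  N   SER A  12      -1.016   0.303  -3.453  1.00  0.00           N  
ATOM     18  CA  SER A  12      -0.709   0.413  -4.866  1.00  0.00           C  
ATOM     19  C   SER A  12      -0.667  -0.959  -5.502  1.00  0.00           C  
ATOM     20  O   SER A  12      -0.570  -1.909  -6.265  1.00  0.00           O  
ATOM     21  CB  SER A  12       0.620   1.142  -5.071  1.00  0.00           C  
ATOM     22  N   VAL A  13      -0.680   2.417   3.152  1.00  0.00           N  
ATOM     23  CA  VAL A  13      -0.240   3.350   4.171  1.00  0.00           C  
ATOM     24  C   VAL A  13      -0.329   4.795   3.688  1.00  0.00           C  
ATOM     25  O   VAL A  13      -0.295   6.027   3.568  1.00  0.00           O  
ATOM     26  CB  VAL A  13       1.192   3.034   4.605  1.00  0.00           C  
ATOM     27  N   LEU A  14      -0.415  -7.247  -1.282  1.00  0.00           N  
ATOM     28  CA  LEU A  14      -1.159  -8.474  -1.485  1.00  0.00           C  
ATOM     29  C   LEU A  14      -1.419  -8.707  -2.961  1.00  0.00           C  
ATOM     30  O   LEU A  14      -1.768  -9.142  -4.054  1.00  0.00           O  
ATOM     31  CB  LEU A  14      -2.479  -8.435  -0.711  1.00  0.00           C  
ATOM     32  N   THR A  15       0.421   6.307  -4.012  1.00  0.00           N  
ATOM     33  CA  THR A  15       1.174   7.327  -4.715  1.00  0.00           C  
ATOM     34  C   THR A  15       1.408   6.937  -6.167  1.00  0.00           C  
ATOM     35  O   THR A  15       1.739   6.883  -7.353  1.00  0.00           O  
ATOM     36  CB  THR A  15       2.512   7.582  -4.017  1.00  0.00           C  
ATOM     37  N   ASN A  16       1.230  -1.865   6.937  1.00  0.00           N  
ATOM     38  CA  ASN A  16       0.739  -2.158   8.269  1.00  0.00           C  
ATOM     39  C   ASN A  16       0.499  -3.646   8.437  1.00  0.00           C  
ATOM     40  O   ASN A  16       0.220  -4.767   8.849  1.00  0.00           O  
ATOM     41  CB  ASN A  16      -0.545  -1.375   8.552  1.00  0.00           C  
ATOM     42  N   GLN A  17       2.095  -3.294  -6.343  1.00  0.00           N  
ATOM     43  CA  GLN A  17       1.873  -4.231  -7.427  1.00  0.00           C  
ATOM     44  C   GLN A  17       1.106  -3.588  -8.580  1.00  0.00           C  
ATOM     45  O   GLN A  17       0.512  -3.338  -9.638  1.00  0.00           O  
ATOM     46  CB  GLN A  17       1.119  -5.464  -6.925  1.00  0.00           C  
ATOM     47  N   ILE A  18       3.338   7.320   2.673  1.00  0.00           N  
ATOM     48  CA  ILE A  18       4.489   8.094   3.099  1.00  0.00           C  
ATOM     49  C   ILE A  18       5.162   8.793   1.921  1.00  0.00           C  
ATOM     50  O   ILE A  18       5.893   9.460   1.179  1.00  0.00           O  
ATOM     51  CB  ILE A  18       5.499   7.199   3.820  1.00  0.00           C  
CONECT    1    2
CONECT    1    3
CONECT    3    4
CONECT    5    6
CONECT    6    7
CONECT    1    8
CONECT    8    9
CONECT    9   10
CONECT    9   11
END   
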