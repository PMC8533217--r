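REMARK   6 SYNTHETIC STAND-IN GENERATED BY mdscape::synthetic_crystal_structure()
REMARK   6 NOT EXPERIMENTAL COORDINATES; EMBEDS PUBLISHED ACTIVE-SITE GEOMETRY ONLY
HETATM    1  FE1 FE  A 501      15.903   4.720   5.353  1.00  0.00          FE
HETATM    2  FE2 FE  A 502      14.424  11.314   6.103  1.00  0.00          FE
ATOM      3  OE1 GLN A 147      -0.310   4.728  20.752  1.00  0.00           O
ATOM      4 HE22 GLN A 147      -2.992   6.513  23.122  1.00  0.00           H
ATOM      5  HE1 TRP A 153       0.250   6.512  20.042  1.00  0.00           H
ATOM      6  OG1 THR A 261      -2.376   8.476  22.341  1.00  0.00           O
HETATM    7  C5  LIG A 401      14.092  -7.028   9.621  1.00  0.00           C
HETATM    8  C8  LIG A 401      13.100  -4.200   8.900  1.00  0.00           C
HETATM    9  C9  LIG A 401      13.529  -2.835   8.357  1.00  0.00           C
HETATM   10  C10 LIG A 401      12.725  -1.709   9.009  1.00  0.00           C
HETATM   11  C11 LIG A 401      11.779  -1.055   8.000  1.00  0.00           C
END
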