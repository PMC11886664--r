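# alpha-cisplatin solid-phase unit-cell content: two cis-[Pt(NH3)2Cl2] units.
# Atom numbering matches the published solid-phase charge table; coordinates
# are synthetic placeholders (the bci solver reads only connectivity).
@<TRIPOS>MOLECULE
alpha_cisplatin
22 20 1 0 0
SMALL
NO_CHARGES

@<TRIPOS>ATOM
      1 Pt1       0.0000     0.0000     0.0000 Pt         1 MOL      0.000000
      2 Pt2       3.1000     3.2000     3.4000 Pt         1 MOL      0.000000
      3 Cl3       2.3300     0.0000     0.0000 Cl         1 MOL      0.000000
      4 Cl4       5.4300     3.2000     3.4000 Cl         1 MOL      0.000000
      5 Cl5       0.0000     2.3300     0.0000 Cl         1 MOL      0.000000
      6 Cl6       3.1000     5.5300     3.4000 Cl         1 MOL      0.000000
      7 N7       -2.0100     0.0000     0.0000 N.3        1 MOL      0.000000
      8 N8        1.0900     3.2000     3.4000 N.3        1 MOL      0.000000
      9 N9        0.0000    -2.0100     0.0000 N.3        1 MOL      0.000000
     10 N10       3.1000     1.1900     3.4000 N.3        1 MOL      0.000000
     11 H11      -2.4000     0.8300     0.4300 H          1 MOL      0.000000
     12 H12       0.7000     4.0300     3.8300 H          1 MOL      0.000000
     13 H13      -2.4000    -0.1700    -0.9400 H          1 MOL      0.000000
     14 H14       0.7000     3.0300     2.4600 H          1 MOL      0.000000
     15 H15      -2.4000    -0.7600     0.5600 H          1 MOL      0.000000
     16 H16       0.7000     2.4400     3.9600 H          1 MOL      0.000000
     17 H17       0.8300    -2.4000     0.4300 H          1 MOL      0.000000
     18 H18       3.9300     0.8000     3.8300 H          1 MOL      0.000000
     19 H19      -0.1700    -2.4000    -0.9400 H          1 MOL      0.000000
     20 H20       2.9300     0.8000     2.4600 H          1 MOL      0.000000
     21 H21      -0.7600    -2.4000     0.5600 H          1 MOL      0.000000
     22 H22       2.3400     0.8000     3.9600 H          1 MOL      0.000000
@<TRIPOS>BOND
     1     1     3 1
     2     1     5 1
     3     1     7 1
     4     1     9 1
     5     2     4 1
     6     2     6 1
     7     2     8 1
     8     2    10 1
     9     7    11 1
    10     7    13 1
    11     7    15 1
    12     8    12 1
    13     8    14 1
    14     8    16 1
    15     9    17 1
    16     9    19 1
    17     9    21 1
    18    10    18 1
    19    10    20 1
    20    10    22 1
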