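# Solid-phase partial atomic charges (e) of alpha-cisplatin (periodic PBE-D3),
# Bader, Hirshfeld and Mulliken population analyses; 22-atom unit-cell content
# (two cis-[Pt(NH3)2Cl2] units), numbering as in alpha_cisplatin.mol2.
atom,Bader,Hirshfeld,Mulliken
Pt1,0.54,0.10,0.19
Pt2,0.54,0.10,0.19
Cl3,-0.54,-0.14,-0.31
Cl4,-0.54,-0.14,-0.31
Cl5,-0.54,-0.15,-0.34
Cl6,-0.54,-0.15,-0.34
N7,-1.19,-0.16,-0.81
N8,-1.19,-0.16,-0.81
N9,-1.21,-0.15,-0.83
N10,-1.21,-0.15,-0.83
H11,0.49,0.08,0.34
H12,0.49,0.08,0.34
H13,0.49,0.08,0.34
H14,0.49,0.08,0.34
H15,0.48,0.08,0.35
H16,0.48,0.08,0.35
H17,0.50,0.08,0.36
H18,0.50,0.08,0.36
H19,0.51,0.08,0.34
H20,0.51,0.08,0.34
H21,0.46,0.09,0.36
H22,0.46,0.09,0.36
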