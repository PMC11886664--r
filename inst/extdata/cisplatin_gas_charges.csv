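# Gas-phase partial atomic charges (e) of cis-[Pt(NH3)2Cl2].
# Levels of theory: DSD-BLYP/Sappo-TZP/DZP (best structural parameters) and
# TPSSh/DKH-TZVP/TZVP (best harmonic frequencies); CHELPG, Hirshfeld and
# Mulliken population analyses.
atom,DSD-BLYP.CHELPG,DSD-BLYP.Hirshfeld,DSD-BLYP.Mulliken,TPSSh.CHELPG,TPSSh.Hirshfeld,TPSSh.Mulliken
Pt,-0.02521,-0.04782,0.11478,-0.01859,-0.01809,0.33260
Cl2,-0.33530,-0.28769,-0.39988,-0.31571,-0.28467,-0.41383
Cl3,-0.33671,-0.28809,-0.40007,-0.31917,-0.28471,-0.41381
N4,-0.39325,-0.09487,-0.06204,-0.42569,-0.10053,-0.54101
N5,-0.40119,-0.09475,-0.06219,-0.42924,-0.10052,-0.54098
H6,0.26015,0.14114,0.12794,0.26935,0.13898,0.26306
H7,0.22269,0.12395,0.14823,0.21318,0.11606,0.26109
H8,0.22688,0.12423,0.14832,0.21666,0.11607,0.26109
H9,0.26098,0.14136,0.12844,0.26946,0.13919,0.26423
H10,0.25938,0.14135,0.12841,0.26952,0.13921,0.26435
H11,0.26158,0.14120,0.12806,0.27023,0.13901,0.26320
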