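# Gas-phase partial atomic charges (e) of the [PtCl4]2- dianion.
# Levels of theory: PBE-QIDH/DKH-TZVPP/TZVP (best structural parameters) and
# PBE-QIDH/def2-QZVP (best harmonic frequencies); CHELPG, Hirshfeld and
# Mulliken population analyses.
atom,PBE-QIDH.DKH.CHELPG,PBE-QIDH.DKH.Hirshfeld,PBE-QIDH.DKH.Mulliken,PBE-QIDH.QZVP.CHELPG,PBE-QIDH.QZVP.Hirshfeld,PBE-QIDH.QZVP.Mulliken
Pt,0.29999,-0.16918,0.28027,0.44168,-0.15493,0.85077
Cl2,-0.57397,-0.45771,-0.57007,-0.60937,-0.46117,-0.71269
Cl3,-0.57527,-0.45771,-0.57007,-0.61090,-0.46129,-0.71269
Cl4,-0.57510,-0.45771,-0.57007,-0.61038,-0.46117,-0.71270
Cl5,-0.57566,-0.45770,-0.57007,-0.61102,-0.46144,-0.71269
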