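# bcifit

Bond charge increments (bci) from partial atomic charges by least squares.

## The problem

The MMFF94 force field builds partial atomic charges additively: the charge
of atom *j* is its atom-type formal charge plus one signed increment per
covalent bond,

    q_j = q0_{I_j} + sum over bonds j-k of  w_{I_k I_j},

where `I_j` is the atom type of atom *j* and the bond charge increment
`w_{I_k I_j}` is the charge shifted onto atom *j* along the `j-k` bond.
Antisymmetry `w_{IJ} = -w_{JI}` makes one number per *bond type* (unordered
pair of atom types) sufficient. MMFF94 has no parameters for platinum, which
matters for modelling cisplatin and other Pt(II) anticancer complexes:
deriving them requires inverting the charge rule.

`bcifit` solves that inverse problem. Given a structure's connectivity and a
set of quantum-chemically derived partial charges (CHELPG, Mulliken,
Hirshfeld, Bader, ...), it assembles the bond-type incidence system
`B w = q - q0` — one row per atom, one integer column per bond type, every
column summing to zero — and finds the least-squares `w`, using the SVD with
minimum-norm completion for rank-deficient (highly symmetric) systems. It
also provides the forward charge-assignment rule, per-bond-type statistics
across structures and charge methods, `.par` parameter files, the RD / MAPE /
MAD benchmark metrics used to score calculated structural parameters against
experiment, and a synthetic-molecule generator with known ground-truth
increments for solver validation.

Increments are reported for canonical keys `lo-hi` (C-locale order of the
type labels) as the increment received by the `lo` atom; for the platinum
complexes this is the ligand-side atom, so `Cl-Pt` < 0 means charge flows
from Pt to Cl.

## Worked example

Cisplatin (cis-[Pt(NH3)2Cl2]: Pt bonded to two Cl and two N, each N carrying
three H) with the DSD-BLYP/Sappo-TZP/DZP CHELPG charges shipped in the
package:

```r
library(bcifit)
cis  <- read_mol2(bci_example("cisplatin.mol2"))[[1]]
qtab <- cisplatin_gas_charges()
fit  <- bci_fit(cis, charges = qtab["DSD-BLYP.CHELPG"], element_types = TRUE)
coef(fit)
#>     Cl-Pt       H-N      N-Pt
#> -0.336005  0.248610  0.348610
```

Charge is pulled from Pt onto Cl (`Cl-Pt` = -0.336 e), pushed from Pt onto N
(`N-Pt` = +0.349 e) and from N onto H (`H-N` = +0.249 e) — the polarity
pattern expected for a soft Pt(II) centre with anionic chloride and dative
amine ligands. Fitting all six packaged charge columns at once aggregates
per-key statistics:

```r
fit6 <- bci_fit(cis, charges = qtab, element_types = TRUE)
fit6$stats
#>   lo hi   key n       mean         sd        min        max
#> 1 Cl Pt Cl-Pt 6 -0.3399700 0.05539986 -0.4138191 -0.2846900
#> 2  H  N   H-N 6  0.1941175 0.06609460  0.1314200  0.2628376
#> 3  N Pt  N-Pt 6  0.3118308 0.03737427  0.2475186  0.3486100
```

`summary(fit)` adds rank and net-charge diagnostics, `predict(fit, mol)`
applies the increments to a structure, `write_par(fit, "cisplatin.par")`
writes the parameter table. For the [PtCl4]2- dianion fitted with all-zero
formal charges the diagnostics flag the structural inconsistency (the -2 e
net charge cannot be represented by increments, whose columns sum to zero):

```r
pt <- read_mol2(bci_example("ptcl4.mol2"))[[1]]
f  <- bci_fit(pt, charges = ptcl4_gas_charges()[["PBE-QIDH.DKH.CHELPG"]],
              element_types = TRUE)
coef(f)                #> Cl-Pt -0.174998
bci_diagnostics(f)     # net_mismatch -2.0, rss 0.80 >= lower bound 0.80, warning
```

Benchmark metrics on the packaged cisplatin-polymorph lattice parameters:

```r
lat  <- lattice_parameters()
beta <- subset(lat, polymorph == "beta")
mape(beta$expt, beta$calc)   #> 0.9366941
```

A command-line front end (`inst/cli/bcifit.R`; subcommands `solve`, `apply`,
`metrics`, `simulate`) wraps the same functions for shell pipelines:

```sh
Rscript $(Rscript -e 'cat(system.file("cli","bcifit.R",package="bcifit"))') \
  solve cisplatin.mol2 --charges charges.txt --element-types --out out/
```

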