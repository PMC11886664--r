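Package: bcifit
Title: Bond Charge Increments from Partial Atomic Charges by Least Squares
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Derives MMFF94-style bond charge increments (bci) from partial
    atomic charges of molecular structures by solving the bond-type incidence
    least-squares system. Reads and writes TRIPOS mol2 files and plain-text
    charge tables, maps bonds to canonical bond-type keys under the bci
    antisymmetry convention, solves per-structure or pooled systems by
    singular value decomposition with minimum-norm completion, applies the
    forward MMFF94 charge-assignment rule, aggregates per-bond-type
    statistics across structures and charge methods, and computes the
    relative-deviation (RD), MAPE and MAD benchmark metrics. Ships the
    connectivity and published partial-charge tables of cisplatin and
    tetrachloroplatinate as worked fixtures, plus a synthetic molecule
    generator with known ground-truth increments for solver validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils, graphics
Suggests: testthat (>= 3.0.0), bio3d, MASS, withr, jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
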