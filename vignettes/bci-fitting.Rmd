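---
title: "Fitting bond charge increments from partial atomic charges"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fitting bond charge increments from partial atomic charges}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bcifit)
```

## The model

MMFF94 assigns partial atomic charges additively. Writing $I_j$ for the atom
type of atom $j$ and $q^0_I$ for the formal charge of type $I$,

$$ q_j = q^0_{I_j} + \sum_{k:\,j\sim k} \omega_{I_k I_j}, $$

where $\omega_{I_k I_j}$, the *bond charge increment* (bci), is the charge
shifted onto atom $j$ along the $j$–$k$ bond, and
$\omega_{IJ} = -\omega_{JI}$. Stacking these equations over the atoms of a
structure gives the linear system

$$ B\,\omega = q - q^0 $$

with one row per atom and one column per *non-degenerate bond-type key*
(unordered pair of distinct atom types). Row $j$ of column $IJ$ counts,
with sign, the bonds at atom $j$ of that type. Two structural facts follow
immediately and are exploited throughout:

* every column of $B$ sums to zero (each bond contributes $+1$ and $-1$),
  so $\mathbf{1}^\top(B\omega) = 0$: increments can never change the total
  charge, and a net charge $\sum q - \sum q^0 \neq 0$ makes the system
  inconsistent with residual sum of squares at least
  $(\sum q - \sum q^0)^2 / n_\text{atoms}$;
* homotype bonds ($I = J$) carry no unknown, since antisymmetry forces
  $\omega_{II} = 0$; their atoms' charges go entirely to the residual.

Given quantum-chemically derived charges $q$ (CHELPG, Mulliken, Hirshfeld,
Bader, ...), `bci_fit()` recovers $\omega$ by unweighted least squares.
This inverse route is how MMFF94's own increments were parametrised, and it
is the practical way to extend the charge model to elements the force field
does not cover — here, platinum(II) complexes.

## Orientation convention

Antisymmetry leaves a global sign choice open. `bcifit` canonicalises every
key by sorting the two type labels in C-locale lexicographic order
(`"Cl-Pt"`, `"H-N"`, `"N-Pt"`) and stores $\omega$ as the increment
**received by the lower-sorting type**. For bonds to a metal centre the
lower type is the ligand-side atom, so the signs read naturally:
`Cl-Pt` $<0$ means the chloride withdraws charge from platinum. The `.par`
writer documents the convention in its header, and a globally flipped
convention would negate every increment while leaving residuals unchanged
(covered by a test).

## Solving: SVD with minimum-norm completion

$B$ is a small dense integer matrix (atoms × bond types), so the solver
computes its SVD and discards singular values below `tol = 1e-10` (relative
to the largest) when forming the pseudoinverse solution. For full-rank
systems this equals the normal-equations solution
$(B^\top B)^{-1} B^\top (q - q^0)$ — the test suite checks agreement to
1e-10 against that independently coded oracle, and against `MASS::ginv` on
rank-deficient cases. For rank-deficient systems (possible in highly
symmetric structures; a triangle of three mutually bonded distinct types is
the smallest example) the minimum-norm least-squares solution is returned,
with the effective rank reported, so symmetric and degenerate molecules
solve deterministically rather than depending on pivoting order.

Per-structure mode (default) solves each molecule/charge-set combination
independently and aggregates per-key mean, sd, min, max and count — the way
increments from different levels of theory or different structures are
compared. Pooled mode stacks all atom rows into one system sharing a single
$\omega$; it is the right tool when several structures are believed to share
exact increments. No row or structure weighting is applied in either mode:
unweighted least squares is the stated estimator, and weights would be an
undocumented extension.

## Formal charges and ionic species

The formal-charge scheme $q^0$ defaults to all zeros, including for ions
such as [PtCl4]$^{2-}$. This is a deliberate choice: the net charge then
appears as an explicit, quantified diagnostic (net-charge mismatch, rss
lower bound, warning) instead of being silently redistributed by some ad hoc
rule, and the resulting increments for the platinum fixtures fall inside the
published gas-phase ranges. Users who prefer ionic formal charges can supply
a scheme (`q0_scheme(Pt = 2, Cl = -1)` or a config file); every atom type
not named resolves to zero unless the scheme is `strict`.

## Tunable parameters

| parameter | default | units | meaning |
|---|---|---|---|
| `tol` | 1e-10 | relative | singular-value cutoff for rank determination |
| `element_types` | `FALSE` | — | collapse SYBYL types (`N.3`) to element symbols (`N`) before keying |
| `mode` | per-structure | — | independent solves + statistics vs one pooled system |
| `q0` | all zeros | e | formal-charge scheme |
| `mismatch_tol` | 1e-3 | e | net-charge mismatch above which diagnostics warn |

`element_types = TRUE` is the natural setting for metal complexes: MMFF94
defines no Pt type, and the chemistry of interest is at the element level
(Pt–Cl vs Pt–N vs N–H). Verbatim typing is the default because user-supplied
labels must pass through untouched.

## File formats

* **mol2 (read/write)** — TRIPOS `MOLECULE`/`ATOM`/`BOND` records only;
  other record types are skipped with a notice. Charges come from ATOM
  column 9; a `NO_CHARGES` tag (or a missing column) flags charges as
  *absent* rather than reading zeros silently, and fitting such a molecule
  without an override is an error. Coordinates are carried through and never
  interpreted. Atom order is preserved verbatim; no result depends on it
  (permutation invariance is tested).
* **charge overrides** — plain text, either `(index, charge)` rows in any
  order (indices must be a permutation of 1..n) or a bare charge column in
  atom order; `#` comments; whitespace or comma separated.
* **.par output** — one row per key: `type_lo type_hi bci n sd`, fixed
  5-decimal formatting for byte-stable reruns, header documenting the
  orientation convention.

## Benchmark metrics

`relative_deviation()` is $100(calc - ref)/ref$, signed so that a
calculated value below the reference is negative; `mape()` is the mean of
its absolute values over a series (used for structural parameters);
`mean_abs_dev()` is the unscaled mean absolute deviation (used for
vibrational frequencies, where percentages would overweight low-frequency
modes). `deviation_report()` combines them for a labelled table, excluding
zero-reference entries from the percent metrics with a warning. Percent
metrics are displayed at 3 decimals, matching how such tables are usually
printed; full precision is kept internally. The packaged lattice-parameter
table for the cisplatin polymorphs reproduces its published deviations
(e.g. MAPE 0.937 % over the six beta-polymorph parameters); the module
computes over whatever series it is given and leaves any pooling of
mixed-unit quantities to the caller.

## The synthetic generator, and what passing tests mean

`random_molecule()` emulates exactly what the solver consumes: a connected
bond graph (sequential-attachment random tree, plus optional extra edges to
exercise cycles), types drawn from an alphabet, and charges produced by the
forward rule from a known increment table plus independent Gaussian noise
per atom. The noise is a stand-in for the spread among charge methods and
levels of theory — it is not a mechanistic model of any of them, and the
generator makes no attempt at realistic geometry, electronegativity
ordering, or correlated errors. Passing recovery tests therefore
demonstrates the *estimator* (exact inversion at zero noise on identified
systems; unbiasedness under zero-mean noise, |bias| < 0.01 e at noise
0.05 e over 200 structures), not the chemical accuracy of any particular
charge method.

`recovery_experiment()` aggregates bias and RMSE over full-column-rank
solves only, reporting the count of rank-deficient draws separately: a
structure that does not identify its increments contributes a minimum-norm
estimate biased toward zero by construction, which would say nothing about
the estimator on identified systems. Ensemble sizes in the tests (10–500
structures of 6–15 atoms) keep the whole suite in seconds while leaving
Monte-Carlo error far below the asserted bounds.

## Numerical and degenerate-input choices

* Rank cutoff 1e-10 (relative): integer matrices with entries of magnitude
  a few units leave an enormous gap between true singular values and noise,
  so the cutoff is uncritical over many orders of magnitude.
* Zero-unknown systems (no bonds, or all bonds homotype) return an empty
  increment vector with the full charge vector as residual — valid output,
  not an error; the generator additionally warns when it produces one.
* Ties in type ordering cannot occur (labels are compared as byte strings);
  keys join labels with `-`, so labels themselves should avoid `-`
  (SYBYL types do).
* Report ordering is canonical key order; solve-internal ordering is
  first-appearance order over the bond list. Both are deterministic.

## The command-line layer

The package is also a shell tool: `inst/cli/bcifit.R` exposes `solve`
(mol2 + optional charge overrides → `.par` files, statistics CSV,
diagnostics, optional plots), `apply` (`.par` + mol2 → mol2 with computed
charges), `metrics` (label/ref/calc CSV → deviations + MAPE/MAD) and
`simulate` (generator + recovery report), with deterministic outputs given
inputs and `--seed`. Configuration is by flags only; the flag set is small
enough that a config-file layer would add surface without capability. Plot
artifacts never affect numeric outputs.

## Known limitations

* No perception of bond orders, aromaticity, protonation or MMFF94 atom
  typing: types are taken as given, connectivity as drawn.
* Formal charges are not fitted jointly with increments; no regularised or
  weighted variants; no angle/dihedral charge increments.
* The solid-phase fixture carries placeholder coordinates; only its
  connectivity, numbering and published charges are meaningful.
* mol2 support covers the records the solver needs; SDF/PDB/XYZ are out of
  scope.
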