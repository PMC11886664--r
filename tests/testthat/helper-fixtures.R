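# Shared fixture builders for the test suite. Everything is generated in
# code; the packaged extdata files are exercised through bci_example().

cisplatin_fixture <- function() read_mol2(bci_example("cisplatin.mol2"), quiet = TRUE)[[1]]
ptcl4_fixture <- function() read_mol2(bci_example("ptcl4.mol2"), quiet = TRUE)[[1]]

# heteronuclear diatomic A-B with given charges; under the canonical
# orientation (+omega to the lower type) the defaults solve to omega = +0.3
diatomic <- function(qa = 0.3, qb = -0.3, ta = "A", tb = "B") {
  molecule("diatomic",
           atoms = data.frame(atom_type = c(ta, tb), charge = c(qa, qb)),
           bonds = data.frame(a = 1, b = 2))
}

# triangle A-B-C: its three bond-type columns are linearly dependent
# (col(A-C) = col(A-B) - col(B-C)), giving a rank-deficient system
triangle <- function(charges = c(0, 0, 0)) {
  molecule("triangle",
           atoms = data.frame(atom_type = c("A", "B", "C"), charge = charges),
           bonds = data.frame(a = c(1, 2, 3), b = c(2, 3, 1)))
}

# apply a permutation to atom order (and remap bonds), optionally shuffle bonds
permute_molecule <- function(m, perm, bond_perm = NULL) {
  inv <- order(perm)
  atoms <- m$atoms[perm, , drop = FALSE]
  rownames(atoms) <- NULL
  bonds <- m$bonds
  bonds$a <- inv[bonds$a]
  bonds$b <- inv[bonds$b]
  if (!is.null(bond_perm)) bonds <- bonds[bond_perm, , drop = FALSE]
  rownames(bonds) <- NULL
  molecule(m$name, atoms, bonds, has_charges = m$has_charges)
}

# explicit normal-equations oracle, independent of the SVD path
normal_eq_omega <- function(sys) {
  unname(drop(solve(crossprod(sys$B), crossprod(sys$B, sys$rhs))))
}
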