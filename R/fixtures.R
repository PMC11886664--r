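#' Packaged platinum-complex fixtures
#'
#' The package ships the worked examples used throughout its documentation
#' and tests: the connectivities of cisplatin (cis-[Pt(NH3)2Cl2], 11 atoms,
#' 10 bonds), tetrachloroplatinate [PtCl4]2- (5 atoms, 4 bonds) and the
#' alpha-cisplatin solid-phase unit-cell content (two cisplatin units, 22
#' atoms), together with published partial-charge tables and the
#' experimental-vs-calculated lattice parameters of the two cisplatin
#' polymorphs. Atom coordinates in the mol2 fixtures are synthetic
#' placeholders (the solver never reads them); connectivity, atom numbering
#' and all charge values follow the published tables digit for digit.
#'
#' @param file fixture file name, or NULL to list the available files.
#' @return \code{bci_example}: a path (or the file listing).
#' @examples
#' bci_example()
#' read_mol2(bci_example("cisplatin.mol2"))[[1]]
#' @name fixtures
NULL

#' @rdname fixtures
#' @export
bci_example <- function(file = NULL) {
  root <- system.file("extdata", package = "bcifit")
  if (is.null(file)) return(list.files(root, recursive = TRUE))
  path <- file.path(root, file)
  if (!file.exists(path)) stop("no packaged fixture '", file, "'")
  path
}

read_fixture_csv <- function(file, first_as_rownames = TRUE) {
  df <- utils::read.csv(bci_example(file), comment.char = "#",
                        check.names = FALSE, stringsAsFactors = FALSE)
  if (first_as_rownames) {
    rownames(df) <- df[[1L]]
    df[[1L]] <- NULL
  }
  df
}

#' @details \code{cisplatin_gas_charges} returns the gas-phase cisplatin
#'   partial charges (e), one row per atom (Pt, Cl2, Cl3, N4, N5, H6-H11)
#'   and one column per level-of-theory/charge-method combination:
#'   DSD-BLYP/Sappo-TZP/DZP and TPSSh/DKH-TZVP/TZVP, each with CHELPG,
#'   Hirshfeld and Mulliken columns.
#' @rdname fixtures
#' @export
cisplatin_gas_charges <- function() read_fixture_csv("cisplatin_gas_charges.csv")

#' @details \code{ptcl4_gas_charges} returns the gas-phase [PtCl4]2-
#'   charges: PBE-QIDH/DKH-TZVPP/TZVP and PBE-QIDH/def2-QZVP, each with
#'   CHELPG, Hirshfeld and Mulliken columns.
#' @rdname fixtures
#' @export
ptcl4_gas_charges <- function() read_fixture_csv("ptcl4_gas_charges.csv")

#' @details \code{alpha_cisplatin_charges} returns the solid-phase
#'   alpha-cisplatin charges (Bader, Hirshfeld, Mulliken), one row per atom
#'   of the 22-atom unit-cell content.
#' @rdname fixtures
#' @export
alpha_cisplatin_charges <- function() read_fixture_csv("alpha_cisplatin_solid_charges.csv")

#' @details \code{lattice_parameters} returns the experimental and
#'   calculated (PBE-D3 periodic DFT) lattice parameters of the alpha and
#'   beta cisplatin polymorphs: columns \code{polymorph}, \code{parameter},
#'   \code{unit}, \code{expt}, \code{calc}.
#' @rdname fixtures
#' @export
lattice_parameters <- function() read_fixture_csv("lattice_parameters.csv",
                                                  first_as_rownames = FALSE)
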