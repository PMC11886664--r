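#' Construct a molecule
#'
#' A molecule is the solver's unit of input: an ordered list of typed atoms
#' carrying partial charges, plus a bond list. Connectivity and atom types are
#' all the bci machinery needs; coordinates, when present, are carried through
#' untouched and never interpreted.
#'
#' @param name molecule name (single string).
#' @param atoms data frame with one row per atom. Recognised columns:
#'   \code{name} (atom label), \code{atom_type} (SYBYL type string or any
#'   user label; required, non-empty), \code{charge} (partial charge in
#'   elementary-charge units e; defaults to 0), \code{formal_charge}
#'   (e; defaults to 0), and optional \code{x}, \code{y}, \code{z}
#'   coordinates, carried verbatim.
#' @param bonds data frame with integer columns \code{a}, \code{b}
#'   (1-based atom indices) and optional \code{order} (mol2 bond-type label,
#'   carried through, not interpreted). May have zero rows.
#' @param has_charges logical; \code{FALSE} marks the charge column as absent
#'   data (all zeros written on output) rather than genuinely neutral atoms.
#'
#' @return An object of class \code{"molecule"}: a list with elements
#'   \code{name}, \code{atoms}, \code{bonds}, \code{has_charges}.
#' @examples
#' m <- molecule("HCl",
#'   atoms = data.frame(name = c("H1", "Cl1"), atom_type = c("H", "Cl"),
#'                      charge = c(0.2, -0.2)),
#'   bonds = data.frame(a = 1, b = 2))
#' total_charge(m)
#' @export
molecule <- function(name, atoms, bonds = data.frame(a = integer(), b = integer()),
                     has_charges = TRUE) {
  stopifnot(is.character(name), length(name) == 1L)
  atoms <- as.data.frame(atoms)
  bonds <- as.data.frame(bonds)
  n <- nrow(atoms)
  if (n < 1L) stop("molecule '", name, "': needs at least one atom")
  if (is.null(atoms$atom_type)) stop("molecule '", name, "': atoms need an 'atom_type' column")
  atoms$atom_type <- as.character(atoms$atom_type)
  if (any(is.na(atoms$atom_type)) || any(!nzchar(atoms$atom_type)))
    stop("molecule '", name, "': empty atom_type")
  if (is.null(atoms$name)) atoms$name <- atoms$atom_type
  if (is.null(atoms$charge)) atoms$charge <- 0
  atoms$charge <- as.numeric(atoms$charge)
  if (any(!is.finite(atoms$charge)))
    stop("molecule '", name, "': non-finite partial charge")
  if (is.null(atoms$formal_charge)) atoms$formal_charge <- 0
  if (any(!is.finite(atoms$formal_charge)))
    stop("molecule '", name, "': non-finite formal charge")
  if (is.null(atoms$element)) atoms$element <- infer_element(atoms$atom_type, atoms$name)

  if (nrow(bonds) > 0L) {
    bonds$a <- as.integer(bonds$a)
    bonds$b <- as.integer(bonds$b)
    if (any(is.na(bonds$a)) || any(is.na(bonds$b)))
      stop("molecule '", name, "': non-integer bond endpoint")
    if (any(bonds$a == bonds$b))
      stop("molecule '", name, "': bond joining an atom to itself")
    if (any(bonds$a < 1L | bonds$a > n | bonds$b < 1L | bonds$b > n))
      stop("molecule '", name, "': bond references a nonexistent atom index")
    key <- paste(pmin(bonds$a, bonds$b), pmax(bonds$a, bonds$b))
    if (anyDuplicated(key))
      stop("molecule '", name, "': duplicate bond between atoms ",
           key[duplicated(key)][1L])
  }
  if (is.null(bonds$order)) bonds$order <- rep("1", nrow(bonds))
  bonds$order <- as.character(bonds$order)

  structure(list(name = name, atoms = atoms, bonds = bonds,
                 has_charges = isTRUE(has_charges)),
            class = "molecule")
}

# Element symbol from the SYBYL type string (text before '.'), falling back to
# the atom name when the type carries no letters. Pt and other metals have no
# standard SYBYL type, so user labels pass through untouched.
infer_element <- function(atom_type, name) {
  lead <- sub("^([A-Za-z]+).*$", "\\1", sub("\\..*$", "", atom_type))
  bad <- !grepl("^[A-Za-z]", atom_type)
  if (any(bad))
    lead[bad] <- sub("^([A-Za-z]+).*$", "\\1", name[bad])
  lead
}

#' Total charge of a molecule
#'
#' Recomputed as the sum of the atomic partial charges, never stored.
#' @param m a \code{\link{molecule}}.
#' @return numeric scalar (e).
#' @export
total_charge <- function(m) {
  stopifnot(inherits(m, "molecule"))
  sum(m$atoms$charge)
}

#' Replace the partial charges of a molecule
#'
#' @param m a \code{\link{molecule}}.
#' @param charges numeric vector, one value per atom in atom order.
#' @return the molecule with the new charges and \code{has_charges = TRUE}.
#' @export
set_charges <- function(m, charges) {
  stopifnot(inherits(m, "molecule"))
  charges <- as.numeric(charges)
  if (length(charges) != nrow(m$atoms))
    stop("charge vector has length ", length(charges), " but molecule '",
         m$name, "' has ", nrow(m$atoms), " atoms")
  if (any(!is.finite(charges))) stop("non-finite charge value")
  m$atoms$charge <- charges
  m$has_charges <- TRUE
  m
}

#' @export
print.molecule <- function(x, ...) {
  cat("molecule '", x$name, "': ", nrow(x$atoms), " atoms, ",
      nrow(x$bonds), " bonds", sep = "")
  if (!x$has_charges) {
    cat(" (no charges)\n")
  } else {
    cat(sprintf(", total charge %+.4f e\n", total_charge(x)))
  }
  types <- table(x$atoms$atom_type)
  cat("  types:", paste(sprintf("%s(%d)", names(types), types), collapse = " "), "\n")
  invisible(x)
}
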