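#' Canonical bond-type key
#'
#' A bond charge increment is antisymmetric in its two atom types:
#' \eqn{\omega_{IJ} = -\omega_{JI}}. To store one number per bond type, keys
#' are canonicalised by sorting the two type labels in C-locale lexicographic
#' order, and the stored \eqn{\omega} is defined as the increment received by
#' the atom of the \emph{lower} type (so for a Pt--Cl bond the key is
#' \code{(Cl, Pt)} and \eqn{\omega} is the charge shifted onto Cl). For
#' homotype pairs antisymmetry forces \eqn{\omega_{II} = 0}; those keys are
#' degenerate and carry no unknown.
#'
#' @param type_a,type_b atom-type labels (non-empty strings, vectorised).
#' @return data frame with columns \code{lo}, \code{hi}, \code{key}
#'   (\code{"lo-hi"}), \code{orientation} (+1 when \code{(type_a, type_b)}
#'   was already canonical, -1 when swapped) and \code{degenerate}.
#' @examples
#' canonical_bond_type("Pt", "Cl")   # key Cl-Pt, orientation -1
#' canonical_bond_type("N", "N")     # degenerate, no unknown
#' @export
canonical_bond_type <- function(type_a, type_b) {
  stopifnot(length(type_a) == length(type_b),
            all(nzchar(type_a)), all(nzchar(type_b)))
  # radix comparison = C locale, independent of the session locale
  swap <- vapply(seq_along(type_a), function(i) {
    s <- sort(c(type_a[i], type_b[i]), method = "radix")
    !identical(s, c(type_a[i], type_b[i]))
  }, NA)
  deg <- type_a == type_b
  lo <- ifelse(swap, type_b, type_a)
  hi <- ifelse(swap, type_a, type_b)
  data.frame(lo = lo, hi = hi, key = paste(lo, hi, sep = "-"),
             orientation = ifelse(swap & !deg, -1L, 1L),
             degenerate = deg, stringsAsFactors = FALSE)
}

# working type labels of a molecule: verbatim SYBYL/user types, or collapsed
# to element symbols (MMFF94 has no Pt type; the Pt complexes are typed at
# the chemical-identity level Pt-Cl, Pt-N, N-H)
working_types <- function(m, element_types = FALSE) {
  if (element_types) m$atoms$element else m$atoms$atom_type
}

#' Enumerate the bond types of a molecule
#'
#' Lists the distinct non-degenerate bond-type keys in order of first
#' appearance along the bond list; each is one unknown of the least-squares
#' system. Degenerate (homotype) keys are reported in the
#' \code{"degenerate"} attribute.
#'
#' @param m a \code{\link{molecule}}.
#' @param element_types collapse atom types to element symbols before keying.
#' @return data frame (columns \code{lo}, \code{hi}, \code{key}), one row per
#'   unknown; attribute \code{degenerate} holds homotype keys present.
#' @examples
#' cis <- read_mol2(system.file("extdata", "cisplatin.mol2", package = "bcifit"))[[1]]
#' bond_type_keys(cis, element_types = TRUE)   # Cl-Pt, N-Pt, H-N
#' @export
bond_type_keys <- function(m, element_types = FALSE) {
  stopifnot(inherits(m, "molecule"))
  ty <- working_types(m, element_types)
  if (nrow(m$bonds) == 0L) {
    out <- data.frame(lo = character(), hi = character(), key = character())
    attr(out, "degenerate") <- character()
    return(out)
  }
  ck <- canonical_bond_type(ty[m$bonds$a], ty[m$bonds$b])
  live <- ck[!ck$degenerate, c("lo", "hi", "key")]
  out <- live[!duplicated(live$key), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "degenerate") <- unique(ck$key[ck$degenerate])
  out
}

#' Formal-charge scheme
#'
#' MMFF94 assigns each atom type an integral or fractional formal charge
#' \eqn{q^0} before bond-increment adjustments. The default scheme is all
#' zeros, the convention used for the platinum-complex fits shipped with the
#' package (for ionic species the net charge then shows up as an explicit
#' residual diagnostic rather than being redistributed).
#'
#' @param ... named formal charges, e.g. \code{q0_scheme(Pt = 2, Cl = -1)},
#'   or a single named numeric vector/list.
#' @param strict when TRUE, resolving a type absent from the mapping is an
#'   error instead of defaulting to 0.
#' @return object of class \code{"q0_scheme"}.
#' @export
q0_scheme <- function(..., strict = FALSE) {
  dots <- list(...)
  if (length(dots) == 1L && is.null(names(dots)) && !is.null(names(dots[[1L]])))
    dots <- as.list(dots[[1L]])
  vals <- vapply(dots, as.numeric, 0)
  if (length(vals) && (is.null(names(vals)) || any(!nzchar(names(vals)))))
    stop("q0_scheme entries must be named by atom type")
  if (any(!is.finite(vals))) stop("non-finite formal charge in scheme")
  structure(list(map = vals, strict = isTRUE(strict)), class = "q0_scheme")
}

#' Read a formal-charge scheme from a config file
#'
#' Plain-text rows \code{"atom_type  q0"}; \code{#} starts a comment.
#' @param x path or character lines.
#' @param strict passed to \code{\link{q0_scheme}}.
#' @return a \code{q0_scheme}.
#' @export
read_q0_scheme <- function(x, strict = FALSE) {
  lines <- as_lines(x)
  lines <- lines[nzchar(trimws(lines)) & !grepl("^\\s*#", lines)]
  rows <- lapply(gsub(",", " ", lines, fixed = TRUE), split_fields)
  if (any(vapply(rows, length, 0L) != 2L))
    stop("formal-charge scheme rows must be 'atom_type q0'")
  vals <- suppressWarnings(as.numeric(vapply(rows, `[`, "", 2L)))
  if (any(is.na(vals))) stop("non-numeric formal charge in scheme file")
  names(vals) <- vapply(rows, `[`, "", 1L)
  if (anyDuplicated(names(vals)))
    stop("duplicate atom type '", names(vals)[duplicated(names(vals))][1L],
         "' in scheme file")
  q0_scheme(vals, strict = strict)
}

#' Formal-charge vector for a molecule
#'
#' @param m a \code{\link{molecule}}.
#' @param scheme a \code{\link{q0_scheme}} (NULL = all zeros).
#' @param element_types resolve against element symbols instead of verbatim
#'   atom types (must match how the fit keys its bond types).
#' @return numeric vector aligned with atom order (e).
#' @export
q0_vector <- function(m, scheme = NULL, element_types = FALSE) {
  stopifnot(inherits(m, "molecule"))
  ty <- working_types(m, element_types)
  if (is.null(scheme)) return(numeric(length(ty)))
  stopifnot(inherits(scheme, "q0_scheme"))
  hit <- match(ty, names(scheme$map))
  if (scheme$strict && anyNA(hit))
    stop("formal-charge scheme does not resolve atom type(s): ",
         paste(unique(ty[is.na(hit)]), collapse = ", "))
  out <- scheme$map[hit]
  out[is.na(hit)] <- 0
  unname(out)
}
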