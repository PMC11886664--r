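#' Read TRIPOS mol2 structures
#'
#' Parses the MOLECULE, ATOM and BOND records of a TRIPOS mol2 document into
#' \code{\link{molecule}} objects. Other record types (SUBSTRUCTURE, CRYSIN,
#' ...) are skipped with a message. A file may hold several MOLECULE records;
#' all are returned. Atom and bond order is preserved verbatim.
#'
#' Charges are taken from column 9 of the ATOM records. When the MOLECULE
#' record declares \code{NO_CHARGES}, or the charge column is missing, charges
#' are set to 0 and the molecule is flagged \code{has_charges = FALSE} so that
#' "no data" is never confused with "neutral".
#'
#' @param x path to a mol2 file, or a character vector holding mol2 text
#'   (either one string with newlines or one element per line).
#' @param quiet suppress the message listing skipped record types.
#' @return list of \code{\link{molecule}} objects.
#' @examples
#' path <- system.file("extdata", "cisplatin.mol2", package = "bcifit")
#' mols <- read_mol2(path)
#' mols[[1]]
#' @seealso \code{\link{write_mol2}}, \code{\link{read_charges}}
#' @export
read_mol2 <- function(x, quiet = FALSE) {
  lines <- as_lines(x)
  starts <- grep("^\\s*@<TRIPOS>MOLECULE\\s*$", lines)
  if (length(starts) == 0L)
    stop("no @<TRIPOS>MOLECULE record found")
  ends <- c(starts[-1L] - 1L, length(lines))
  skipped <- character()
  mols <- vector("list", length(starts))
  for (i in seq_along(starts)) {
    block <- lines[starts[i]:ends[i]]
    parsed <- parse_molecule_block(block)
    skipped <- union(skipped, parsed$skipped)
    mols[[i]] <- parsed$molecule
  }
  if (!quiet && length(skipped))
    message("read_mol2: skipping record type(s) ", paste(skipped, collapse = ", "))
  mols
}

as_lines <- function(x) {
  if (length(x) == 1L && !grepl("\n", x) && file.exists(x)) {
    lines <- readLines(x, warn = FALSE)
  } else {
    lines <- unlist(strsplit(x, "\n", fixed = TRUE), use.names = FALSE)
  }
  # tolerate CRLF and stray trailing whitespace
  sub("[\r[:space:]]+$", "", lines)
}

split_fields <- function(line) strsplit(trimws(line), "[[:space:]]+")[[1L]]

parse_molecule_block <- function(block) {
  # block[1] is the @<TRIPOS>MOLECULE tag
  body <- block[-1L]
  nonblank <- which(nzchar(trimws(body)) & !grepl("^\\s*#", body))
  if (length(nonblank) < 2L) stop("truncated MOLECULE record")
  mol_name <- trimws(body[nonblank[1L]])
  counts <- suppressWarnings(as.integer(split_fields(body[nonblank[2L]])))
  if (length(counts) < 1L || is.na(counts[1L]))
    stop("MOLECULE record '", mol_name, "': unreadable atom/bond counts")
  n_atoms <- counts[1L]
  n_bonds <- if (length(counts) >= 2L && !is.na(counts[2L])) counts[2L] else 0L
  charge_tag <- if (length(nonblank) >= 4L) trimws(body[nonblank[4L]]) else "NO_CHARGES"

  tags <- grep("^@<TRIPOS>", body)
  tag_names <- sub("^@<TRIPOS>", "", body[tags])
  section <- function(what) {
    hit <- which(tag_names == what)
    if (length(hit) == 0L) return(character())
    from <- tags[hit[1L]] + 1L
    to <- if (hit[1L] < length(tags)) tags[hit[1L] + 1L] - 1L else length(body)
    if (to < from) return(character())
    sec <- body[from:to]
    sec[nzchar(trimws(sec)) & !grepl("^\\s*#", sec)]
  }
  skipped <- setdiff(tag_names, c("ATOM", "BOND"))

  atom_lines <- section("ATOM")
  if (length(atom_lines) != n_atoms)
    stop("MOLECULE record '", mol_name, "': declares ", n_atoms,
         " atoms but ATOM section lists ", length(atom_lines))
  bond_lines <- section("BOND")
  if (length(bond_lines) != n_bonds)
    stop("MOLECULE record '", mol_name, "': declares ", n_bonds,
         " bonds but BOND section lists ", length(bond_lines))

  af <- lapply(atom_lines, split_fields)
  nf <- vapply(af, length, 0L)
  if (any(nf < 6L))
    stop("MOLECULE record '", mol_name, "': ATOM line with fewer than 6 fields")
  has_charges <- all(nf >= 9L) && !identical(toupper(charge_tag), "NO_CHARGES")
  num <- function(k) vapply(af, function(f) suppressWarnings(as.numeric(f[k])), 0)
  atoms <- data.frame(
    name = vapply(af, `[`, "", 2L),
    x = num(3L), y = num(4L), z = num(5L),
    atom_type = vapply(af, `[`, "", 6L),
    charge = if (has_charges) num(9L) else 0,
    stringsAsFactors = FALSE)
  if (has_charges && any(!is.finite(atoms$charge)))
    stop("MOLECULE record '", mol_name, "': non-numeric charge in ATOM section")

  if (n_bonds > 0L) {
    bf <- lapply(bond_lines, split_fields)
    if (any(vapply(bf, length, 0L) < 4L))
      stop("MOLECULE record '", mol_name, "': BOND line with fewer than 4 fields")
    bonds <- data.frame(
      a = vapply(bf, function(f) suppressWarnings(as.integer(f[2L])), 0L),
      b = vapply(bf, function(f) suppressWarnings(as.integer(f[3L])), 0L),
      order = vapply(bf, `[`, "", 4L),
      stringsAsFactors = FALSE)
  } else {
    bonds <- data.frame(a = integer(), b = integer(), order = character())
  }

  list(molecule = molecule(mol_name, atoms, bonds, has_charges = has_charges),
       skipped = skipped)
}

#' Write a molecule as TRIPOS mol2
#'
#' Round-trip safe: \code{read_mol2(write_mol2(m))} reproduces names, types,
#' bonds and charges (charges to 1e-6 e, the printed precision). Molecules
#' flagged as charge-free are written with the \code{NO_CHARGES} tag and a
#' zero charge column.
#'
#' @param m a \code{\link{molecule}}.
#' @param file optional path; when omitted the document is returned as a
#'   character vector of lines.
#' @return invisibly, the mol2 lines.
#' @export
write_mol2 <- function(m, file = NULL) {
  stopifnot(inherits(m, "molecule"))
  a <- m$atoms
  n <- nrow(a)
  xyz <- function(col) if (!is.null(a[[col]]) && all(is.finite(a[[col]]))) a[[col]] else rep(0, n)
  lines <- c(
    "@<TRIPOS>MOLECULE",
    m$name,
    sprintf("%d %d 0 0 0", n, nrow(m$bonds)),
    "SMALL",
    if (m$has_charges) "USER_CHARGES" else "NO_CHARGES",
    "",
    "@<TRIPOS>ATOM",
    sprintf("%7d %-8s %10.4f %10.4f %10.4f %-8s %3d %-8s %10.6f",
            seq_len(n), a$name, xyz("x"), xyz("y"), xyz("z"),
            a$atom_type, 1L, "MOL", if (m$has_charges) a$charge else rep(0, n)),
    "@<TRIPOS>BOND")
  if (nrow(m$bonds) > 0L)
    lines <- c(lines, sprintf("%6d %5d %5d %s",
                              seq_len(nrow(m$bonds)), m$bonds$a, m$bonds$b, m$bonds$order))
  if (!is.null(file)) writeLines(lines, file)
  invisible(lines)
}

#' Read an external charge table
#'
#' Charge-set files carry one partial charge per atom, exported from
#' electronic-structure population analyses (CHELPG, Mulliken, Hirshfeld,
#' Bader, ...). Two layouts are accepted: two columns \code{(atom index,
#' charge)} in any row order, or a bare column of charges in atom order.
#' Fields may be separated by whitespace or commas; lines starting with
#' \code{#} are comments.
#'
#' @param x path or character vector of lines.
#' @return numeric charge vector in atom order (e).
#' @examples
#' read_charges(c("# two-column form", "2 0.3", "1 -0.3"))
#' read_charges(c("-0.3", "0.3"))
#' @export
read_charges <- function(x) {
  lines <- as_lines(x)
  lines <- lines[nzchar(trimws(lines)) & !grepl("^\\s*#", lines)]
  if (length(lines) == 0L) stop("charge table is empty")
  rows <- lapply(gsub(",", " ", lines, fixed = TRUE), split_fields)
  nf <- unique(vapply(rows, length, 0L))
  if (length(nf) != 1L || !nf %in% c(1L, 2L))
    stop("charge table must have one or two columns throughout")
  if (nf == 1L) {
    q <- suppressWarnings(as.numeric(vapply(rows, `[`, "", 1L)))
    if (any(is.na(q))) stop("non-numeric charge in charge table")
    return(q)
  }
  idx <- suppressWarnings(as.integer(vapply(rows, `[`, "", 1L)))
  q <- suppressWarnings(as.numeric(vapply(rows, `[`, "", 2L)))
  if (any(is.na(idx))) stop("non-integer atom index in charge table")
  if (any(is.na(q))) stop("non-numeric charge in charge table")
  if (anyDuplicated(idx))
    stop("duplicate atom index ", idx[duplicated(idx)][1L], " in charge table")
  if (!setequal(idx, seq_along(idx)))
    stop("atom indices are not a permutation of 1..", length(idx))
  out <- numeric(length(idx))
  out[idx] <- q
  out
}
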