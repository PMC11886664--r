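#' Build the bond-type incidence least-squares system
#'
#' The MMFF94 charge rule writes each partial atomic charge as the atom's
#' formal charge plus the signed bond charge increments of its incident
#' bonds. For one structure this is the linear system \eqn{B \omega = q - q^0}
#' with one row per atom and one column per non-degenerate bond-type key.
#' Row j holds, for each key, (number of bonds at atom j where j is on the
#' lower-type side) minus (number where it is on the higher-type side), so
#' every column sums to exactly zero and all entries are integers.
#'
#' @param m a \code{\link{molecule}}.
#' @param q0 a \code{\link{q0_scheme}} or NULL (all-zero formal charges).
#' @param element_types collapse atom types to element symbols.
#' @param charges optional replacement partial-charge vector.
#' @return object of class \code{"bci_system"}: list with the integer matrix
#'   \code{B}, right-hand side \code{rhs} (= q - q0), the \code{keys} data
#'   frame, \code{q0} vector, and bookkeeping fields.
#' @examples
#' cis <- read_mol2(system.file("extdata", "cisplatin.mol2", package = "bcifit"))[[1]]
#' sys <- bci_system(cis, element_types = TRUE)
#' colSums(sys$B)   # all zero, structurally
#' @export
bci_system <- function(m, q0 = NULL, element_types = FALSE, charges = NULL) {
  stopifnot(inherits(m, "molecule"))
  if (!is.null(charges)) m <- set_charges(m, charges)
  ty <- working_types(m, element_types)
  keys <- bond_type_keys(m, element_types)
  n <- nrow(m$atoms)
  B <- matrix(0L, n, nrow(keys), dimnames = list(NULL, keys$key))
  if (nrow(m$bonds) > 0L && nrow(keys) > 0L) {
    ck <- canonical_bond_type(ty[m$bonds$a], ty[m$bonds$b])
    for (i in seq_len(nrow(m$bonds))) {
      if (ck$degenerate[i]) next
      j <- match(ck$key[i], keys$key)
      lo_atom <- if (ty[m$bonds$a[i]] == ck$lo[i]) m$bonds$a[i] else m$bonds$b[i]
      hi_atom <- if (lo_atom == m$bonds$a[i]) m$bonds$b[i] else m$bonds$a[i]
      B[lo_atom, j] <- B[lo_atom, j] + 1L
      B[hi_atom, j] <- B[hi_atom, j] - 1L
    }
  }
  q0v <- q0_vector(m, q0, element_types)
  structure(list(B = B, rhs = m$atoms$charge - q0v, keys = keys, q0 = q0v,
                 molecule = m$name, n_atoms = n,
                 has_charges = m$has_charges),
            class = "bci_system")
}

# minimum-norm least squares via SVD; rank from relative singular-value
# cutoff so symmetric/degenerate structures solve deterministically
solve_lsq <- function(B, rhs, tol = 1e-10) {
  k <- ncol(B)
  if (k == 0L) {
    return(list(omega = numeric(0), residuals = -rhs, rss = sum(rhs^2), rank = 0L))
  }
  sv <- svd(B)
  keep <- sv$d > tol * max(sv$d, 0)
  rank <- sum(keep)
  omega <- if (rank == 0L) numeric(k) else
    sv$v[, keep, drop = FALSE] %*%
      ((crossprod(sv$u[, keep, drop = FALSE], rhs)) / sv$d[keep])
  omega <- drop(omega)
  if (length(omega) != k) omega <- rep(0, k)  # rank-0 guard
  res <- drop(B %*% omega) - rhs
  list(omega = stats::setNames(omega, colnames(B)),
       residuals = res, rss = sum(res^2), rank = rank)
}

solve_system <- function(sys, tol = 1e-10) {
  stopifnot(inherits(sys, "bci_system"))
  ls <- solve_lsq(sys$B, sys$rhs, tol)
  list(molecule = sys$molecule, charge_set = NA_character_,
       keys = sys$keys, omega = ls$omega, residuals = ls$residuals,
       rss = ls$rss, rank = ls$rank, n_unknowns = ncol(sys$B),
       n_atoms = sys$n_atoms,
       net_mismatch = sum(sys$rhs))
}

#' Fit bond charge increments by least squares
#'
#' The central fitting function. Given one or more molecules whose atoms
#' carry partial charges (from the mol2 file, from \code{charges} overrides,
#' or both), it builds the bond-type incidence system of each structure and
#' solves \eqn{\min_\omega \|B\omega - (q - q^0)\|^2} by singular value
#' decomposition, returning the minimum-norm solution when a system is
#' rank-deficient.
#'
#' In \code{"per-structure"} mode (the default) every molecule / charge-set
#' combination is solved independently and per-key statistics (n, mean, sd,
#' min, max) are aggregated across the solutions, which is how increments
#' derived from several levels of theory or several structures are usually
#' compared. In \code{"pooled"} mode all atom rows are stacked into a single
#' system sharing one \eqn{\omega} vector, solved once.
#'
#' @param molecules a \code{\link{molecule}} or list of molecules.
#' @param charges optional partial-charge override: a numeric vector (one
#'   molecule), a matrix/data frame with one column per charge set (one
#'   molecule, several charge methods), or a list of such objects matching
#'   \code{molecules}. NULL uses the charges stored in each molecule.
#' @param q0 a \code{\link{q0_scheme}}; NULL means all formal charges zero.
#' @param mode \code{"per-structure"} or \code{"pooled"}.
#' @param element_types collapse atom types to element symbols before keying
#'   bond types (e.g. \code{N.3} and \code{N.4} both become \code{N}).
#' @param tol relative singular-value cutoff for rank determination.
#' @return object of class \code{"bci_fit"} with components
#'   \code{solutions} (one entry per solve: omega, residuals, rss, rank,
#'   net-charge mismatch), \code{stats} (per-key aggregate data frame) and
#'   the call/settings. \code{coef()} extracts the per-key mean increment,
#'   \code{predict()} applies the increments to a molecule,
#'   \code{summary()} adds diagnostics.
#' @examples
#' cis <- read_mol2(system.file("extdata", "cisplatin.mol2", package = "bcifit"))[[1]]
#' qtab <- cisplatin_gas_charges()
#' fit <- bci_fit(cis, charges = qtab["DSD-BLYP.CHELPG"], element_types = TRUE)
#' coef(fit)   # Cl-Pt ~ -0.336, N-Pt ~ +0.349, H-N ~ +0.249
#' @seealso \code{\link{apply_bci}}, \code{\link{write_par}},
#'   \code{\link{bci_diagnostics}}
#' @export
bci_fit <- function(molecules, charges = NULL, q0 = NULL,
                    mode = c("per-structure", "pooled"),
                    element_types = FALSE, tol = 1e-10) {
  mode <- match.arg(mode)
  if (inherits(molecules, "molecule")) molecules <- list(molecules)
  stopifnot(length(molecules) >= 1L,
            all(vapply(molecules, inherits, NA, "molecule")))

  cases <- expand_cases(molecules, charges)
  systems <- lapply(cases, function(cs)
    bci_system(cs$molecule, q0 = q0, element_types = element_types,
               charges = cs$charges))
  for (i in seq_along(systems)) {
    if (is.null(cases[[i]]$charges) && !systems[[i]]$has_charges)
      stop("molecule '", systems[[i]]$molecule,
           "' carries no charges and no override was given")
  }

  if (mode == "pooled") {
    pooled <- pool_systems(systems)
    ls <- solve_lsq(pooled$B, pooled$rhs, tol)
    sol <- list(molecule = "pooled", charge_set = "pooled",
                keys = pooled$keys, omega = ls$omega,
                residuals = ls$residuals, rss = ls$rss, rank = ls$rank,
                n_unknowns = ncol(pooled$B), n_atoms = nrow(pooled$B),
                net_mismatch = sum(pooled$rhs))
    solutions <- list(sol)
  } else {
    solutions <- lapply(seq_along(systems), function(i) {
      s <- solve_system(systems[[i]], tol)
      s$charge_set <- cases[[i]]$label
      s
    })
  }

  structure(list(solutions = solutions,
                 stats = aggregate_omega(solutions),
                 mode = mode, element_types = element_types, tol = tol,
                 call = match.call()),
            class = "bci_fit")
}

# normalise the molecules/charges combination into solve cases
expand_cases <- function(molecules, charges) {
  mk <- function(m, q, label) list(molecule = m, charges = q, label = label)
  if (is.null(charges))
    return(lapply(molecules, mk, q = NULL, label = "input"))
  if (is.numeric(charges) && is.null(dim(charges))) {
    if (length(molecules) != 1L)
      stop("a single charge vector needs a single molecule")
    return(list(mk(molecules[[1L]], charges, "override")))
  }
  if (is.matrix(charges) || is.data.frame(charges)) {
    if (length(molecules) != 1L)
      stop("a charge matrix needs a single molecule")
    labs <- colnames(charges)
    if (is.null(labs)) labs <- paste0("set", seq_len(ncol(charges)))
    return(lapply(seq_len(ncol(charges)), function(j)
      mk(molecules[[1L]], as.numeric(charges[[j]]), labs[j])))
  }
  if (is.list(charges)) {
    if (length(charges) != length(molecules))
      stop("charge list length must match the number of molecules")
    out <- list()
    for (i in seq_along(molecules)) {
      sub <- expand_cases(molecules[i], charges[[i]])
      for (cs in sub) {
        cs$label <- paste0(molecules[[i]]$name, ":", cs$label)
        out[[length(out) + 1L]] <- cs
      }
    }
    return(out)
  }
  stop("unsupported 'charges' argument")
}

pool_systems <- function(systems) {
  keys <- do.call(rbind, lapply(systems, function(s) s$keys))
  keys <- keys[!duplicated(keys$key), , drop = FALSE]
  rownames(keys) <- NULL
  B <- do.call(rbind, lapply(systems, function(s) {
    big <- matrix(0L, nrow(s$B), nrow(keys), dimnames = list(NULL, keys$key))
    if (ncol(s$B) > 0L) big[, colnames(s$B)] <- s$B
    big
  }))
  list(B = B, rhs = unlist(lapply(systems, `[[`, "rhs"), use.names = FALSE),
       keys = keys)
}

aggregate_omega <- function(solutions) {
  keyinfo <- do.call(rbind, lapply(solutions, function(s) s$keys))
  keyinfo <- keyinfo[!duplicated(keyinfo$key), , drop = FALSE]
  if (nrow(keyinfo) == 0L)
    return(data.frame(lo = character(), hi = character(), key = character(),
                      n = integer(), mean = numeric(), sd = numeric(),
                      min = numeric(), max = numeric()))
  # deterministic report ordering: canonical (C-locale) key sort
  keyinfo <- keyinfo[order(keyinfo$key, method = "radix"), , drop = FALSE]
  rows <- lapply(seq_len(nrow(keyinfo)), function(i) {
    vals <- unlist(lapply(solutions, function(s) s$omega[keyinfo$key[i]]),
                   use.names = FALSE)
    vals <- vals[!is.na(vals)]
    data.frame(lo = keyinfo$lo[i], hi = keyinfo$hi[i], key = keyinfo$key[i],
               n = length(vals), mean = mean(vals),
               sd = if (length(vals) > 1L) stats::sd(vals) else 0,
               min = min(vals), max = max(vals), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' @export
coef.bci_fit <- function(object, ...) {
  stats::setNames(object$stats$mean, object$stats$key)
}

#' @export
residuals.bci_fit <- function(object, ...) {
  if (length(object$solutions) == 1L) return(object$solutions[[1L]]$residuals)
  stats::setNames(lapply(object$solutions, `[[`, "residuals"),
                  vapply(object$solutions, `[[`, "", "charge_set"))
}

#' @export
print.bci_fit <- function(x, digits = 5, ...) {
  cat("Bond charge increment fit (", x$mode, " mode, ",
      length(x$solutions), " solve", if (length(x$solutions) != 1L) "s",
      ")\n", sep = "")
  cat("omega = increment received by the first (lexicographically lower) atom type\n\n")
  st <- x$stats
  st[c("mean", "sd", "min", "max")] <- lapply(st[c("mean", "sd", "min", "max")],
                                              round, digits)
  print(st, row.names = FALSE)
  invisible(x)
}

#' Solver diagnostics
#'
#' Reports, per solve, the effective rank against the number of unknowns,
#' the net-charge mismatch \eqn{\sum q - \sum q^0}, the residual sum of
#' squares with its structural lower bound, and the largest per-atom
#' residual. Because every column of the incidence matrix sums to zero, a
#' nonzero net-charge mismatch can never be fitted: the system is then
#' necessarily inconsistent and \eqn{rss \ge (\sum q - \sum q^0)^2 / n}
#' no matter the increments. Mismatches beyond \code{mismatch_tol} raise a
#' warning (typical for ionic species fitted with all-zero formal charges).
#'
#' @param fit a \code{\link{bci_fit}}.
#' @param mismatch_tol absolute net-charge mismatch (e) above which the
#'   inconsistency warning fires.
#' @param warn emit the warning (set FALSE to just collect the table).
#' @return data frame, one row per solve.
#' @export
bci_diagnostics <- function(fit, mismatch_tol = 1e-3, warn = TRUE) {
  stopifnot(inherits(fit, "bci_fit"))
  rows <- lapply(fit$solutions, function(s) {
    data.frame(molecule = s$molecule, charge_set = s$charge_set,
               n_atoms = s$n_atoms, n_unknowns = s$n_unknowns,
               rank = s$rank, rss = s$rss,
               rss_lower_bound = s$net_mismatch^2 / s$n_atoms,
               net_mismatch = s$net_mismatch,
               max_abs_residual = if (length(s$residuals)) max(abs(s$residuals)) else 0,
               inconsistent = abs(s$net_mismatch) > mismatch_tol,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  if (warn && any(out$inconsistent)) {
    bad <- out[out$inconsistent, , drop = FALSE]
    warning("inconsistent system(s): net charge mismatch ",
            paste(sprintf("%s/%s = %+.4f e (rss >= %.4f)", bad$molecule,
                          bad$charge_set, bad$net_mismatch,
                          bad$rss_lower_bound), collapse = "; "),
            "; the incidence columns sum to zero, so this charge cannot be fitted",
            call. = FALSE)
  }
  out
}

#' @export
summary.bci_fit <- function(object, ...) {
  structure(list(stats = object$stats,
                 diagnostics = bci_diagnostics(object, warn = FALSE),
                 mode = object$mode, call = object$call),
            class = "summary.bci_fit")
}

#' @export
print.summary.bci_fit <- function(x, digits = 5, ...) {
  cat("Call: ", deparse(x$call), "\n\n", sep = "")
  cat("Per-key increments (", x$mode, " mode):\n", sep = "")
  st <- x$stats
  st[c("mean", "sd", "min", "max")] <- lapply(st[c("mean", "sd", "min", "max")],
                                              round, digits)
  print(st, row.names = FALSE)
  cat("\nDiagnostics:\n")
  d <- x$diagnostics
  d[c("rss", "rss_lower_bound", "net_mismatch", "max_abs_residual")] <-
    lapply(d[c("rss", "rss_lower_bound", "net_mismatch", "max_abs_residual")],
           signif, 4)
  print(d, row.names = FALSE)
  if (any(x$diagnostics$inconsistent))
    cat("\nNote: solves marked inconsistent have a net charge that no",
        "increment vector can reproduce (columns of B sum to zero).\n")
  invisible(x)
}

#' Apply bond charge increments to a molecule (forward MMFF94 rule)
#'
#' Computes \eqn{q_j = q^0_j + \sum_{bonds\ j-k} \pm\omega}, the MMFF94
#' charge-assignment rule: along each non-degenerate bond the lower-type
#' atom receives \eqn{+\omega} and the higher-type atom \eqn{-\omega}.
#' By construction the output charges sum exactly to \eqn{\sum q^0},
#' whatever the increments.
#'
#' @param m a \code{\link{molecule}}.
#' @param omega named numeric vector keyed \code{"lo-hi"}, a data frame with
#'   columns \code{lo}, \code{hi}, \code{bci} (as from \code{\link{read_par}}),
#'   or a \code{\link{bci_fit}} (its \code{coef()} is used).
#' @param q0 a \code{\link{q0_scheme}} or NULL.
#' @param element_types must match the setting used when solving.
#' @return numeric vector of partial charges in atom order (e).
#' @examples
#' m <- molecule("AB", data.frame(atom_type = c("A", "B")), data.frame(a = 1, b = 2))
#' apply_bci(m, c("A-B" = 0.3))   # -> +0.3 on A, -0.3 on B
#' @export
apply_bci <- function(m, omega, q0 = NULL, element_types = FALSE) {
  stopifnot(inherits(m, "molecule"))
  if (inherits(omega, "bci_fit")) {
    if (missing(element_types)) element_types <- omega$element_types
    omega <- coef(omega)
  }
  if (is.data.frame(omega)) {
    val_col <- intersect(c("bci", "mean", "omega"), names(omega))[1L]
    if (is.na(val_col)) stop("omega data frame needs a 'bci' column")
    omega <- stats::setNames(omega[[val_col]], paste(omega$lo, omega$hi, sep = "-"))
  }
  ty <- working_types(m, element_types)
  q <- q0_vector(m, q0, element_types)
  if (nrow(m$bonds) == 0L) return(q)
  ck <- canonical_bond_type(ty[m$bonds$a], ty[m$bonds$b])
  need <- unique(ck$key[!ck$degenerate])
  missing_keys <- setdiff(need, names(omega))
  if (length(missing_keys))
    stop("no increment supplied for bond type(s): ",
         paste(missing_keys, collapse = ", "))
  for (i in seq_len(nrow(m$bonds))) {
    if (ck$degenerate[i]) next
    w <- omega[[ck$key[i]]]
    lo_atom <- if (ty[m$bonds$a[i]] == ck$lo[i]) m$bonds$a[i] else m$bonds$b[i]
    hi_atom <- if (lo_atom == m$bonds$a[i]) m$bonds$b[i] else m$bonds$a[i]
    q[lo_atom] <- q[lo_atom] + w
    q[hi_atom] <- q[hi_atom] - w
  }
  q
}

#' @param object a \code{\link{bci_fit}}.
#' @param newdata a \code{\link{molecule}} to assign charges to.
#' @param q0 a \code{\link{q0_scheme}} or NULL.
#' @param ... unused.
#' @rdname apply_bci
#' @export
predict.bci_fit <- function(object, newdata, q0 = NULL, ...) {
  apply_bci(newdata, coef(object), q0 = q0,
            element_types = object$element_types)
}

#' Per-key increment variation plot
#'
#' One strip per bond-type key showing the increments obtained across the
#' individual solves (structures and/or charge sets), with the mean marked.
#' @param x a \code{\link{bci_fit}}.
#' @param ... passed to \code{stripchart}.
#' @export
plot.bci_fit <- function(x, ...) {
  vals <- lapply(x$stats$key, function(k)
    unlist(lapply(x$solutions, function(s) s$omega[k]), use.names = FALSE))
  vals <- lapply(vals, function(v) v[!is.na(v)])
  names(vals) <- x$stats$key
  graphics::stripchart(vals, vertical = TRUE, method = "jitter", pch = 1,
                       ylab = "bond charge increment (e)", ...)
  graphics::points(seq_along(vals), x$stats$mean, pch = 19, col = 2)
  graphics::abline(h = 0, lty = 3)
  invisible(x)
}
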