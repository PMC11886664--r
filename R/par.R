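#' Write a bond-charge-increment parameter file
#'
#' Plain-text .par table, one row per bond-type key with columns
#' \code{type_lo type_hi bci n sd}, values at fixed 5-decimal formatting so
#' reruns are byte-identical. The header documents the orientation
#' convention.
#'
#' @param x a \code{\link{bci_fit}}, its \code{stats} data frame, or a named
#'   increment vector keyed \code{"lo-hi"}.
#' @param file output path, or NULL to return the lines.
#' @return invisibly, the lines written.
#' @seealso \code{\link{read_par}}
#' @export
write_par <- function(x, file = NULL) {
  if (inherits(x, "bci_fit")) x <- x$stats
  if (is.numeric(x) && !is.null(names(x))) {
    parts <- strsplit(names(x), "-", fixed = TRUE)
    x <- data.frame(lo = vapply(parts, `[`, "", 1L),
                    hi = vapply(parts, `[`, "", 2L),
                    mean = unname(x), n = 1L, sd = 0)
  }
  stopifnot(is.data.frame(x), all(c("lo", "hi", "mean") %in% names(x)))
  if (is.null(x$n)) x$n <- 1L
  if (is.null(x$sd)) x$sd <- 0
  lines <- c(
    "# bond charge increment parameters (e)",
    "# convention: bci is the increment received by the first-named atom type;",
    "#             the second-named atom receives -bci (antisymmetry)",
    "# type_lo type_hi      bci    n       sd",
    sprintf("%-8s %-8s %9.5f %4d %9.5f", x$lo, x$hi, x$mean, x$n, x$sd))
  if (!is.null(file)) writeLines(lines, file)
  invisible(lines)
}

#' Read a .par parameter file
#'
#' @param x path or character lines, in the format written by
#'   \code{\link{write_par}}.
#' @return data frame with columns \code{lo}, \code{hi}, \code{key},
#'   \code{bci}, \code{n}, \code{sd}; usable directly in
#'   \code{\link{apply_bci}}.
#' @export
read_par <- function(x) {
  lines <- as_lines(x)
  lines <- lines[nzchar(trimws(lines)) & !grepl("^\\s*#", lines)]
  if (length(lines) == 0L) stop("empty .par file")
  rows <- lapply(lines, split_fields)
  if (any(vapply(rows, length, 0L) < 3L))
    stop(".par rows must be 'type_lo type_hi bci [n sd]'")
  get <- function(k, fallback = NA) vapply(rows, function(f)
    if (length(f) >= k) f[k] else as.character(fallback), "")
  bci <- suppressWarnings(as.numeric(get(3L)))
  if (any(is.na(bci))) stop("non-numeric bci value in .par file")
  lo <- get(1L); hi <- get(2L)
  data.frame(lo = lo, hi = hi, key = paste(lo, hi, sep = "-"), bci = bci,
             n = suppressWarnings(as.integer(get(4L, 1L))),
             sd = suppressWarnings(as.numeric(get(5L, 0))),
             stringsAsFactors = FALSE)
}
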