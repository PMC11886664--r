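#' Relative deviation (percent)
#'
#' \code{100 * (calc - ref) / ref}, signed: a calculated value below the
#' reference gives a negative deviation.
#'
#' @param ref reference values (nonzero).
#' @param calc calculated values, same length and units.
#' @return percent deviations, one per pair.
#' @examples
#' relative_deviation(6.2424, 6.2218)   # -0.330 %
#' @export
relative_deviation <- function(ref, calc) {
  check_pairs(ref, calc)
  if (any(ref == 0))
    stop("relative deviation is undefined for a zero reference value")
  100 * (calc - ref) / ref
}

#' Mean absolute percentage deviation
#'
#' Mean of the absolute \code{\link{relative_deviation}} over the series;
#' the standard accuracy score for structural parameters (lattice constants,
#' bond lengths, angles) against experiment.
#'
#' @inheritParams relative_deviation
#' @return percent scalar.
#' @export
mape <- function(ref, calc) {
  check_pairs(ref, calc)
  mean(abs(relative_deviation(ref, calc)))
}

#' Mean absolute deviation
#'
#' Mean of \code{|calc - ref|} in the input units; used for harmonic
#' vibrational frequencies (cm-1), where a percentage scale would be
#' dominated by the low-frequency modes.
#'
#' @inheritParams relative_deviation
#' @return scalar in the units of the inputs.
#' @export
mean_abs_dev <- function(ref, calc) {
  check_pairs(ref, calc)
  mean(abs(calc - ref))
}

check_pairs <- function(ref, calc) {
  if (length(ref) == 0L) stop("empty series")
  if (length(ref) != length(calc))
    stop("ref and calc must have the same length")
  if (any(!is.finite(ref)) || any(!is.finite(calc)))
    stop("non-finite value in series")
  invisible(TRUE)
}

#' Reference-vs-calculated deviation report
#'
#' Per-entry relative deviations plus the MAPE and MAD summaries for a
#' labelled series. Entries with a zero reference are flagged and excluded
#' from the percent metrics (with a warning); they still enter the MAD,
#' which needs no division.
#'
#' @param ref,calc paired numeric series.
#' @param labels optional entry labels.
#' @return object of class \code{"deviation_report"}: the per-entry data
#'   frame with attributes \code{mape} and \code{mad}.
#' @examples
#' lat <- lattice_parameters()
#' beta <- subset(lat, polymorph == "beta")
#' r <- deviation_report(beta$expt, beta$calc, beta$parameter)
#' attr(r, "mape")   # 0.937
#' @export
deviation_report <- function(ref, calc, labels = NULL) {
  check_pairs(ref, calc)
  if (is.null(labels)) labels <- as.character(seq_along(ref))
  ok <- ref != 0
  if (!all(ok))
    warning(sum(!ok), " entr", if (sum(!ok) == 1L) "y" else "ies",
            " with zero reference excluded from percent metrics", call. = FALSE)
  rd <- rep(NA_real_, length(ref))
  rd[ok] <- relative_deviation(ref[ok], calc[ok])
  out <- data.frame(label = labels, ref = ref, calc = calc, rd = rd,
                    stringsAsFactors = FALSE)
  structure(out, class = c("deviation_report", "data.frame"),
            mape = if (any(ok)) mean(abs(rd[ok])) else NA_real_,
            mad = mean_abs_dev(ref, calc))
}

#' @export
print.deviation_report <- function(x, ...) {
  shown <- as.data.frame(x)
  shown$rd <- round(shown$rd, 3)
  print(shown, row.names = FALSE)
  cat(sprintf("\nMAPE: %.3f %%   MAD: %.4g\n",
              attr(x, "mape"), attr(x, "mad")))
  invisible(x)
}
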