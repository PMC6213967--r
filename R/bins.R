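#' Bin scheme for beta-value and detection p-value distributions
#'
#' A bin scheme fixes the interval edges used to turn per-probe beta-values
#' and detection p-values into per-sample proportion vectors. Intervals are
#' left-open/right-closed, `(e[i], e[i+1]]`, except that the first interval
#' also contains its lower edge so that a value of exactly 0 is not lost.
#'
#' The defaults are the scheme used for routine estimation: 10 beta-value
#' bins of width 0.1, and 3 detection p-value bins with interior edges at
#' 1e-5 and 0.01 (i.e. `p <= 1e-5`, `1e-5 < p <= 0.01`, `0.01 < p <= 1`).
#'
#' @param beta_edges Strictly increasing numeric vector of beta-value bin
#'   edges, starting at 0 and ending at 1.
#' @param detp_edges Strictly increasing numeric vector of detection p-value
#'   bin edges, starting at 0 and ending at 1.
#' @return An object of class `bin_scheme` with elements `beta_edges` and
#'   `detp_edges`.
#' @seealso [fine_bin_scheme()] for the high-resolution scheme used to store
#'   reference panels, [bin_proportions()] for the binning itself.
#' @examples
#' bin_scheme()                        # the default estimation scheme
#' bin_scheme(beta_edges = seq(0, 1, by = 0.2))  # 5 wider beta bins
#' @export
bin_scheme <- function(beta_edges = seq(0, 1, by = 0.1),
                       detp_edges = c(0, 1e-5, 1e-2, 1)) {
  beta_edges <- signif(as.numeric(beta_edges), 12)
  detp_edges <- signif(as.numeric(detp_edges), 12)
  validate_edges(beta_edges, "beta_edges")
  validate_edges(detp_edges, "detp_edges")
  structure(list(beta_edges = beta_edges, detp_edges = detp_edges),
            class = "bin_scheme")
}

validate_edges <- function(edges, what) {
  if (!is.numeric(edges) || length(edges) < 2L || anyNA(edges))
    stop(what, " must be a numeric vector of at least two finite edges")
  if (edges[1L] != 0 || edges[length(edges)] != 1)
    stop(what, " must start at 0 and end at 1")
  if (any(diff(edges) <= 0))
    stop(what, " must be strictly increasing")
  invisible(edges)
}

#' Fine bin scheme used for stored reference panels
#'
#' Reference panels are stored at high resolution so they can be re-binned to
#' any compatible coarser scheme without touching the raw data: 100
#' beta-value bins of width 0.01 (`0 < b <= 0.01`, `0.01 < b <= 0.02`, ...)
#' and 18 detection p-value bins on decade edges (`p <= 1e-17`,
#' `1e-17 < p <= 1e-16`, ..., `0.1 < p <= 1`).
#'
#' @return A `bin_scheme` with 100 beta bins and 18 detection p-value bins.
#' @seealso [rebin()] to collapse a panel stored at this scheme to a coarser
#'   aligned scheme.
#' @export
fine_bin_scheme <- function() {
  bin_scheme(beta_edges = seq(0, 1, by = 0.01),
             detp_edges = c(0, as.numeric(sprintf("1e-%d", 17:1)), 1))
}

n_bins <- function(edges) length(edges) - 1L

#' @export
print.bin_scheme <- function(x, ...) {
  cat("Bin scheme:\n")
  cat("  beta: ", n_bins(x$beta_edges), " bins, edges ",
      paste(format(x$beta_edges, trim = TRUE), collapse = ", "), "\n", sep = "")
  cat("  detp: ", n_bins(x$detp_edges), " bins, edges ",
      paste(format(x$detp_edges, trim = TRUE), collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Proportion of values falling in each bin
#'
#' Counts values into the left-open/right-closed intervals defined by
#' `edges` (the first interval additionally contains its lower edge) and
#' returns the proportions. Missing values are dropped before counting;
#' proportions are relative to the non-missing values, so the result always
#' sums to 1.
#'
#' @param values Numeric vector of values in `[0, 1]`; `NA`s are dropped.
#' @param edges Strictly increasing numeric vector of bin edges covering the
#'   values.
#' @return Numeric vector of length `length(edges) - 1` summing to 1.
#' @examples
#' bin_proportions(c(0.05, 0.15, 0.95), seq(0, 1, by = 0.1))
#' bin_proportions(c(0, 0.1, 0.2), seq(0, 1, by = 0.1))  # edge values
#' @export
bin_proportions <- function(values, edges) {
  if (!is.numeric(values)) stop("values must be numeric")
  v <- values[!is.na(values)]
  if (length(v) == 0L)
    stop("no non-missing values to bin (chromosome absent or all values missing)")
  lo <- edges[1L]
  hi <- edges[length(edges)]
  if (any(v < lo | v > hi))
    stop("values outside the bin range [", lo, ", ", hi, "]")
  idx <- .bincode(v, breaks = edges, right = TRUE, include.lowest = TRUE)
  tabulate(idx, nbins = length(edges) - 1L) / length(v)
}

#' Beta-values from raw methylated/unmethylated signals
#'
#' Computes per-probe methylation beta-values from raw signal intensities as
#' `M / (M + U + offset)`, with a stabilising offset in the denominator that
#' shrinks noisy low-intensity probes towards 0 rather than letting them take
#' arbitrary ratios. Results are clamped to `[0, 1]`.
#'
#' @param methylated Non-negative methylated signal intensities.
#' @param unmethylated Non-negative unmethylated signal intensities
#'   (recycled against `methylated`).
#' @param offset Non-negative stabilising offset added to the denominator;
#'   default 100, the conventional value for Illumina intensity data.
#' @return Numeric vector of beta-values in `[0, 1]`; entries whose
#'   denominator is zero are returned as `NA` with a warning.
#' @examples
#' compute_beta(900, 0, offset = 100)   # 0.9
#' compute_beta(c(0, 500), c(1000, 500), offset = 0)
#' @export
compute_beta <- function(methylated, unmethylated, offset = 100) {
  if (any(methylated < 0, na.rm = TRUE) || any(unmethylated < 0, na.rm = TRUE))
    stop("signal intensities must be non-negative")
  if (length(offset) != 1L || is.na(offset) || offset < 0)
    stop("offset must be a single non-negative number")
  den <- methylated + unmethylated + offset
  beta <- methylated / den
  zero <- !is.na(den) & den == 0
  if (any(zero)) {
    warning(sum(zero), " probe(s) with all-zero signals; beta set to NA")
    beta[zero] <- NA_real_
  }
  pmin(1, pmax(0, beta))
}
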