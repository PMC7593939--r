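#' Correlation histogram bin scheme
#'
#' Partition of the correlation range \[-1, 1\] into equal-width bins. The
#' default is eight 0.25-wide bins, the resolution at which template shapes
#' are defined. Bins are left-closed and right-open, except the last bin
#' which is closed on both sides so that r = 1 maps to a bin.
#'
#' @param n_bins Number of equal-width bins spanning \[-1, 1\]. Default 8.
#'
#' @return An object of class `bin_scheme`: a list with `n_bins`, `edges`
#'   (`n_bins + 1` ascending cut points from -1 to +1) and `midpoints`
#'   (bin centers).
#' @examples
#' bin_scheme()      # eight 0.25-bins
#' bin_scheme(10)    # ten 0.10-bins
#' @export
bin_scheme <- function(n_bins = 8L) {
  n_bins <- as.integer(n_bins)
  if (length(n_bins) != 1L || is.na(n_bins) || n_bins < 2L)
    stop("'n_bins' must be a single integer >= 2")
  edges <- seq(-1, 1, length.out = n_bins + 1L)
  structure(
    list(n_bins = n_bins,
         edges = edges,
         midpoints = (edges[-1L] + edges[-(n_bins + 1L)]) / 2),
    class = "bin_scheme")
}

#' @export
print.bin_scheme <- function(x, ...) {
  cat("Bin scheme:", x$n_bins, "bins of width",
      format(diff(x$edges[1:2])), "on [-1, 1]\n")
  invisible(x)
}

#' Map correlations to histogram bins
#'
#' Assigns each correlation to its bin. Values epsilon-outside \[-1, 1\] from
#' floating-point round-off are clamped so every input maps to exactly one
#' bin.
#'
#' @param r Numeric vector of correlation coefficients.
#' @param scheme A [bin_scheme()].
#' @return `bin_index`: integer bin indices in `1:n_bins`; `bin_counts`:
#'   integer vector of length `n_bins` with the count per bin.
#' @export
bin_index <- function(r, scheme = bin_scheme()) {
  stopifnot(inherits(scheme, "bin_scheme"))
  if (anyNA(r)) stop("correlations must be finite (NA encountered)")
  r <- pmin(pmax(r, -1), 1)
  findInterval(r, scheme$edges, rightmost.closed = TRUE)
}

#' @rdname bin_index
#' @export
bin_counts <- function(r, scheme = bin_scheme()) {
  tabulate(bin_index(r, scheme), nbins = scheme$n_bins)
}
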