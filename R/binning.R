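#' Grey-value binning convention
#'
#' Defines the affine mapping from Hounsfield units (HU) to histogram bins.
#' Bins are half-open intervals `[lo, hi)` of equal width; the first and last
#' bin additionally absorb all values below and above the binning range, as
#' happens when a wide HU range is quantised to a fixed 8-bit grey scale.
#'
#' The default covers `[-512, 512)` HU with 256 bins of 4 HU, placing 0 HU
#' (water) at bin 129.  This keeps both the fat peak (around -80 HU) and the
#' muscle peak (around +50 HU) well inside the range while retaining HU
#' semantics for thresholds and fitted means.
#'
#' @param origin_hu HU value of the lower edge of the first bin.
#' @param width_hu bin width in HU; must be positive.
#' @param n_bins number of bins (256 for 8-bit grey scales).
#' @return An object of class `grey_binning`.
#' @examples
#' b <- grey_binning()
#' bin_index(c(-80, 0, 50), b)
#' @export
grey_binning <- function(origin_hu = -512, width_hu = 4, n_bins = 256) {
  stopifnot(is.numeric(origin_hu), length(origin_hu) == 1L, is.finite(origin_hu))
  if (!is.numeric(width_hu) || length(width_hu) != 1L || !is.finite(width_hu) ||
      width_hu <= 0) {
    stop("`width_hu` must be a single positive number", call. = FALSE)
  }
  n_bins <- as.integer(n_bins)
  if (is.na(n_bins) || n_bins < 2L) {
    stop("`n_bins` must be an integer >= 2", call. = FALSE)
  }
  structure(
    list(origin_hu = origin_hu, width_hu = width_hu, n_bins = n_bins),
    class = "grey_binning"
  )
}

#' @export
print.grey_binning <- function(x, ...) {
  cat(sprintf("<grey_binning> %d bins of %g HU on [%g, %g) HU\n",
              x$n_bins, x$width_hu, x$origin_hu,
              x$origin_hu + x$n_bins * x$width_hu))
  invisible(x)
}

#' Bin index of a grey value
#'
#' Maps HU values to 1-based bin indices.  Values below the binning range fall
#' into bin 1, values at or above the upper edge into bin `n_bins` (the edge
#' bins absorb out-of-range values).
#'
#' @param hu numeric vector of grey values in HU.
#' @param binning a [grey_binning()].
#' @return Integer vector of bin indices in `1:n_bins`.
#' @export
bin_index <- function(hu, binning) {
  stopifnot(inherits(binning, "grey_binning"))
  if (!is.numeric(hu) || anyNA(hu) || any(!is.finite(hu))) {
    stop("`hu` must be finite numeric", call. = FALSE)
  }
  idx <- floor((hu - binning$origin_hu) / binning$width_hu)
  as.integer(pmin(pmax(idx, 0), binning$n_bins - 1L)) + 1L
}

#' Bin edges and centers
#'
#' `bin_edges()` returns the `n_bins + 1` nominal bin edges in HU (the outer
#' edges are nominal only: edge bins absorb all out-of-range mass).
#' `bin_centers()` returns the `n_bins` bin midpoints.
#'
#' @inheritParams bin_index
#' @return Numeric vector of edges (length `n_bins + 1`) or centers
#'   (length `n_bins`).
#' @export
bin_edges <- function(binning) {
  stopifnot(inherits(binning, "grey_binning"))
  binning$origin_hu + binning$width_hu * (0:binning$n_bins)
}

#' @rdname bin_edges
#' @export
bin_centers <- function(binning) {
  stopifnot(inherits(binning, "grey_binning"))
  binning$origin_hu + binning$width_hu * (seq_len(binning$n_bins) - 0.5)
}

# lower/upper integration edges per bin, with the edge bins extended to +-Inf
# so that the tail mass is absorbed there (mass conservation is then exact)
.bin_bounds <- function(binning) {
  e <- bin_edges(binning)
  n <- binning$n_bins
  list(lo = c(-Inf, e[2:n]), hi = c(e[2:n], Inf))
}

.same_binning <- function(a, b) {
  isTRUE(all.equal(a$origin_hu, b$origin_hu)) &&
    isTRUE(all.equal(a$width_hu, b$width_hu)) &&
    a$n_bins == b$n_bins
}
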