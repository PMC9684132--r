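#' Empirical grey-value histogram
#'
#' Container for the per-bin pixel counts \eqn{x_n(Y)} of a CT slice together
#' with its binning convention and the included-bin set \eqn{G_0} over which
#' the weighted least-squares distance is evaluated.  By default all bins are
#' included; bins with zero counts are additionally dropped at evaluation
#' time whenever the weight exponent is negative (the weight
#' \eqn{x_n^\alpha} is undefined at \eqn{x_n = 0} for \eqn{\alpha < 0}).
#'
#' @param counts non-negative per-bin counts (length `n_bins`).  Usually
#'   integer pixel counts; real-valued expected counts are accepted so that
#'   model-generated histograms can be fed back into the fitting routines.
#' @param binning a [grey_binning()].
#' @param included optional logical vector marking the bins of \eqn{G_0};
#'   defaults to all bins.
#' @return An object of class `grey_histogram` with fields `counts`,
#'   `binning`, `included` and `q_total` (the total count \eqn{Q}).
#' @seealso [compute_histogram()] to extract one from a slice image.
#' @export
grey_histogram <- function(counts, binning, included = NULL) {
  stopifnot(inherits(binning, "grey_binning"))
  if (!is.numeric(counts) || length(counts) != binning$n_bins ||
      anyNA(counts) || any(counts < 0)) {
    stop("`counts` must be non-negative and of length `n_bins`", call. = FALSE)
  }
  if (is.null(included)) included <- rep(TRUE, binning$n_bins)
  if (!is.logical(included) || length(included) != binning$n_bins ||
      anyNA(included)) {
    stop("`included` must be logical of length `n_bins`", call. = FALSE)
  }
  structure(
    list(counts = as.numeric(counts), binning = binning,
         included = included, q_total = sum(counts)),
    class = "grey_histogram"
  )
}

#' @export
print.grey_histogram <- function(x, ...) {
  cat(sprintf("<grey_histogram> Q = %g pixels over %d bins (%d occupied, %d in G0)\n",
              x$q_total, x$binning$n_bins, sum(x$counts > 0), sum(x$included)))
  invisible(x)
}

#' Model-expected (theoretical) histogram
#'
#' The expected per-bin counts \eqn{x_n(\Theta) = Q \cdot p_n(\Theta)}, where
#' \eqn{p_n(\Theta)} is the probability mass of bin `n` under the Gaussian
#' mixture, computed as the difference of the mixture CDF at the bin edges.
#' The first and last bin absorb the tail mass below/above the binning range,
#' so the expected counts sum to `q_total` exactly.
#'
#' @param theta a [mixture_params()] object.
#' @param q_total total pixel count \eqn{Q > 0}.
#' @param binning a [grey_binning()].
#' @return An object of class `theoretical_histogram` with fields `expected`,
#'   `binning`, `q_total`.
#' @examples
#' th <- mixture_params(-80, 50, 10, 10, 0.3)
#' xt <- theoretical_histogram(th, 262144, grey_binning())
#' sum(xt$expected)  # exactly Q
#' @export
theoretical_histogram <- function(theta, q_total, binning) {
  .check_theta(theta)
  stopifnot(inherits(binning, "grey_binning"))
  if (!is.numeric(q_total) || length(q_total) != 1L || !is.finite(q_total) ||
      q_total <= 0) {
    stop("`q_total` must be a single positive number", call. = FALSE)
  }
  structure(
    list(expected = q_total * .bin_masses(theta, binning),
         binning = binning, q_total = q_total),
    class = "theoretical_histogram"
  )
}

#' @export
print.theoretical_histogram <- function(x, ...) {
  cat(sprintf("<theoretical_histogram> Q = %g expected pixels over %d bins\n",
              x$q_total, x$binning$n_bins))
  invisible(x)
}
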