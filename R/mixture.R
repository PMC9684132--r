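#' Two-component Gaussian grey-value mixture parameters
#'
#' The parameter vector \eqn{\Theta = (E_F, E_M, S_F, S_M, z)} of the
#' fat/muscle grey-value model: the slice's grey values are modelled as the
#' mixture \eqn{f = z f_F + (1-z) f_M} of two Normal densities, with
#' \eqn{f_F = \phi(\cdot; E_F, S_F)} the fat component and
#' \eqn{f_M = \phi(\cdot; E_M, S_M)} the muscle component, and \eqn{z} the
#' proportion of fat pixels among the fat-or-muscle pixels.
#'
#' The canonical orientation is `e_f < e_m` (fat is darker than muscle on
#' CT).  If the arguments violate it, the constructor swaps the components
#' and replaces `z` by `1 - z`, which leaves the mixture density unchanged.
#'
#' @param e_f fat mean grey value (HU).
#' @param e_m muscle mean grey value (HU).
#' @param s_f,s_m component standard deviations (HU); must be positive.
#' @param z fat pixel proportion in `[0, 1]`.
#' @return An object of class `mixture_params`.
#' @examples
#' mixture_params(-80, 50, 10, 10, 0.3)
#' # canonical orientation is enforced by swapping:
#' mixture_params(50, -80, 10, 10, 0.7)
#' @export
mixture_params <- function(e_f, e_m, s_f, s_m, z) {
  v <- c(e_f = e_f, e_m = e_m, s_f = s_f, s_m = s_m, z = z)
  if (!is.numeric(v) || length(v) != 5L || anyNA(v) || any(!is.finite(v))) {
    stop("mixture parameters must be finite numbers", call. = FALSE)
  }
  if (s_f <= 0 || s_m <= 0) {
    stop("component standard deviations must be positive", call. = FALSE)
  }
  if (z < 0 || z > 1) {
    stop("`z` must lie in [0, 1]", call. = FALSE)
  }
  if (e_f > e_m) {
    tmp <- c(e_m, e_f, s_m, s_f, 1 - z)
    e_f <- tmp[1]; e_m <- tmp[2]; s_f <- tmp[3]; s_m <- tmp[4]; z <- tmp[5]
  }
  structure(
    list(e_f = e_f, e_m = e_m, s_f = s_f, s_m = s_m, z = z),
    class = "mixture_params"
  )
}

#' @export
print.mixture_params <- function(x, ...) {
  cat(sprintf(
    "<mixture_params> E_F = %.6g HU, E_M = %.6g HU, S_F = %.6g HU, S_M = %.6g HU, z = %.6g\n",
    x$e_f, x$e_m, x$s_f, x$s_m, x$z))
  invisible(x)
}

.theta_vec <- function(theta) {
  c(theta$e_f, theta$e_m, theta$s_f, theta$s_m, theta$z)
}

.check_theta <- function(theta) {
  if (!inherits(theta, "mixture_params")) {
    stop("`theta` must be a `mixture_params` object", call. = FALSE)
  }
  invisible(theta)
}

#' Mixture density of the grey-value model
#'
#' Evaluates \eqn{f(g) = z\,\phi(g; E_F, S_F) + (1-z)\,\phi(g; E_M, S_M)}.
#'
#' @param g grey values in HU (numeric vector, finite).
#' @param theta a [mixture_params()] object.
#' @return Density values (unit 1/HU); non-negative, integrating to one.
#' @export
mixture_density <- function(g, theta) {
  .check_theta(theta)
  if (!is.numeric(g) || length(g) == 0L || anyNA(g) || any(!is.finite(g))) {
    stop("`g` must be finite numeric", call. = FALSE)
  }
  theta$z * dnorm(g, theta$e_f, theta$s_f) +
    (1 - theta$z) * dnorm(g, theta$e_m, theta$s_m)
}

# mixture CDF; accepts +-Inf
.mixture_cdf <- function(q, theta) {
  theta$z * pnorm(q, theta$e_f, theta$s_f) +
    (1 - theta$z) * pnorm(q, theta$e_m, theta$s_m)
}

# per-bin mass of one Normal component, switching to the upper tail above
# the mean so that far-tail masses are free of cancellation
.comp_masses <- function(lo, hi, m, s) {
  upper <- lo >= m
  out <- pnorm(hi, m, s) - pnorm(lo, m, s)
  out[upper] <- pnorm(lo[upper], m, s, lower.tail = FALSE) -
    pnorm(hi[upper], m, s, lower.tail = FALSE)
  pmax(out, 0)
}

# per-bin mass of the mixture given a plain parameter vector and bin bounds
.mix_masses_vec <- function(th, bb) {
  th[5] * .comp_masses(bb$lo, bb$hi, th[1], th[3]) +
    (1 - th[5]) * .comp_masses(bb$lo, bb$hi, th[2], th[4])
}

# per-bin probability mass of the mixture under a binning (edge bins absorb
# the tails); sums to 1 exactly up to floating point
.bin_masses <- function(theta, binning) {
  .mix_masses_vec(.theta_vec(theta), .bin_bounds(binning))
}
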