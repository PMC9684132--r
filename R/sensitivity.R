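# Delta-method (Gaussian) sensitivity analysis of the WLS estimator.
#
# The estimator covariance is the standard sandwich form for fixed-weight
# least squares: with J the model Jacobian, W the weight matrix and Sigma
# the covariance of the histogram counts,
#   Cov(Theta*) = (J'WJ)^-1 J'W Sigma WJ (J'WJ)^-1.
# Sigma is taken multinomial, which corresponds to stochastically
# independent pixel grey values with random material assignment.

# d(bin mass)/d(theta), N x 5, exact Gaussian-CDF edge derivatives; edge
# bins (with infinite integration bounds) contribute zero density terms,
# which is exactly the derivative of the absorbed tail mass
.mass_jacobian <- function(th, binning) {
  b <- .bin_bounds(binning)
  lo <- b$lo; hi <- b$hi
  dens <- function(g, m, s) ifelse(is.finite(g), dnorm(g, m, s), 0)
  udens <- function(g, m, s) ifelse(is.finite(g), (g - m) / s * dnorm(g, m, s), 0)
  z <- th[5]
  cbind(
    e_f = z * (dens(lo, th[1], th[3]) - dens(hi, th[1], th[3])),
    e_m = (1 - z) * (dens(lo, th[2], th[4]) - dens(hi, th[2], th[4])),
    s_f = z * (udens(lo, th[1], th[3]) - udens(hi, th[1], th[3])),
    s_m = (1 - z) * (udens(lo, th[2], th[4]) - udens(hi, th[2], th[4])),
    z = .comp_masses(lo, hi, th[1], th[3]) - .comp_masses(lo, hi, th[2], th[4])
  )
}

#' Jacobian of the model histogram
#'
#' The `N x 5` matrix of partial derivatives
#' \eqn{\partial x_n(\Theta) / \partial \Theta_k} of the expected bin counts
#' with respect to \eqn{(E_F, E_M, S_F, S_M, z)}, using exact Gaussian-CDF
#' derivatives at the bin edges.  The edge bins include the derivatives of
#' the absorbed tail mass, so every column sums to zero (the total count
#' \eqn{Q} does not depend on \eqn{\Theta}).
#'
#' @param theta a [mixture_params()].
#' @param q_total total pixel count \eqn{Q}.
#' @param binning a [grey_binning()].
#' @return Numeric matrix with `n_bins` rows and columns
#'   `e_f, e_m, s_f, s_m, z`.
#' @export
model_jacobian <- function(theta, q_total, binning) {
  .check_theta(theta)
  stopifnot(inherits(binning, "grey_binning"))
  q_total * .mass_jacobian(.theta_vec(theta), binning)
}

#' Multinomial covariance of the histogram counts
#'
#' Under stochastically independent pixel grey values the bin counts are
#' multinomial with cell probabilities \eqn{p_n(\Theta)}:
#' \eqn{\mathrm{Var}(x_n) = Q p_n (1 - p_n)},
#' \eqn{\mathrm{Cov}(x_n, x_m) = -Q p_n p_m}.  All row sums are zero.
#'
#' @inheritParams model_jacobian
#' @return `n_bins x n_bins` covariance matrix.
#' @export
histogram_covariance <- function(theta, q_total, binning) {
  .check_theta(theta)
  stopifnot(inherits(binning, "grey_binning"))
  p <- .bin_masses(theta, binning)
  q_total * (diag(p) - outer(p, p))
}

#' Sandwich covariance of the WLS parameter estimator
#'
#' Propagates the histogram covariance through the fixed-weight least-squares
#' normal equations:
#' \deqn{\mathrm{Cov}(\Theta^*) = (J^\top WJ)^{-1} J^\top W \Sigma WJ (J^\top WJ)^{-1}}
#' with \eqn{W = \mathrm{diag}(weights)}.  For weight exponent
#' \eqn{\alpha = 0} the weights are all one and the estimator is ordinary
#' least squares.  If \eqn{J^\top WJ} is numerically singular the
#' Moore-Penrose pseudo-inverse is used and the result carries the attribute
#' `near_singular = TRUE`.
#'
#' @param jacobian `N x 5` model Jacobian from [model_jacobian()].
#' @param hist_cov `N x N` histogram covariance from
#'   [histogram_covariance()].
#' @param weights per-bin weight vector; `NULL` (default) means unit weights.
#' @return Symmetric `5 x 5` covariance matrix of
#'   \eqn{(E_F, E_M, S_F, S_M, z)}.
#' @export
estimator_covariance <- function(jacobian, hist_cov, weights = NULL) {
  if (!is.matrix(jacobian) || ncol(jacobian) != 5L) {
    stop("`jacobian` must be an N x 5 matrix", call. = FALSE)
  }
  n <- nrow(jacobian)
  if (!is.matrix(hist_cov) || !all(dim(hist_cov) == n)) {
    stop("`hist_cov` must be N x N matching the Jacobian", call. = FALSE)
  }
  if (is.null(weights)) weights <- rep(1, n)
  if (length(weights) != n || any(weights < 0)) {
    stop("`weights` must be non-negative of length N", call. = FALSE)
  }
  jw <- weights * jacobian
  a <- crossprod(jacobian, jw)
  near_singular <- !is.finite(rcond(a)) || rcond(a) < 1e-14
  ainv <- if (near_singular) {
    warning("J'WJ is numerically singular; using pseudo-inverse",
            call. = FALSE)
    MASS::ginv(a)
  } else {
    solve(a)
  }
  m <- crossprod(jw, hist_cov %*% jw)
  v <- ainv %*% m %*% ainv
  v <- (v + t(v)) / 2
  dimnames(v) <- list(colnames(jacobian), colnames(jacobian))
  structure(v, near_singular = near_singular)
}

#' Standard deviation of the fat-ratio estimator over a grid of component SDs
#'
#' For each `S` in `s_grid`, builds \eqn{\Theta = (E_F, E_M, S, S, z)},
#' composes [model_jacobian()], [histogram_covariance()] and
#' [estimator_covariance()] with unit weights (weight exponent
#' \eqn{\alpha = 0}, i.e. an LS estimator), and returns
#' \eqn{S(z^*) = \sqrt{\mathrm{Cov}(\Theta^*)_{zz}}}.
#'
#' The default pixel count is the masked pixel count of the 512 x 512
#' concentric-disk phantom, [phantom_mask_count()]`(512)`; it is recorded in
#' the output so that the \eqn{\sqrt{Q}} scale of the curve is explicit.
#'
#' @param s_grid vector of component SDs in HU (positive).
#' @param e_f,e_m component means in HU, `e_f < e_m`.
#' @param z fat ratio in `(0, 1)`.
#' @param q_total total pixel count; default [phantom_mask_count()]`(512)`.
#' @param binning a [grey_binning()].
#' @return Data frame with columns `s`, `z_std`, `q_total`.
#' @examples
#' z_std_curve(c(20, 60, 90), q_total = 1e5)
#' @export
z_std_curve <- function(s_grid, e_f = -80, e_m = 50, z = 0.3,
                        q_total = NULL, binning = grey_binning()) {
  if (length(s_grid) == 0L || any(s_grid <= 0)) {
    stop("`s_grid` must be positive", call. = FALSE)
  }
  if (e_f >= e_m) stop("requires e_f < e_m", call. = FALSE)
  if (is.null(q_total)) q_total <- phantom_mask_count(512)
  z_std <- vapply(s_grid, function(s) {
    th <- mixture_params(e_f, e_m, s, s, z)
    j <- model_jacobian(th, q_total, binning)
    sig <- histogram_covariance(th, q_total, binning)
    v <- estimator_covariance(j, sig)
    sqrt(max(v["z", "z"], 0))
  }, numeric(1))
  data.frame(s = s_grid, z_std = z_std, q_total = q_total)
}
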