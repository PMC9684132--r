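# Weighted least-squares mixture fitting.
#
# The estimator minimizes the WLS distance
#   S_alpha = sum_{n in G0} (x_n(Y) - x_n(Theta))^2 * x_n(Y)^alpha
# over Theta.  The weights are the *empirical* counts raised to alpha and
# are held fixed during optimization.  Optimization runs on transformed
# parameters (means unconstrained, log SDs, logit z), so every iterate is a
# valid mixture; the multi-modality of the objective is handled by a
# deterministic multi-start (quantile splits, histogram modes, seeded
# jitter) with the best final objective winning.

#' Fit configuration
#'
#' @param alpha weight exponent \eqn{\alpha} of the WLS distance.  `alpha = 1`
#'   weights residuals by the empirical counts; `alpha = 0` is ordinary least
#'   squares; negative values down-weight full bins (zero-count bins are then
#'   excluded from the objective).
#' @param binning a [grey_binning()].
#' @param n_restarts number of multi-start initializations (>= 1).
#' @param max_iter iteration cap per restart.
#' @param tol relative convergence tolerance on the objective.
#' @param seed integer seed for the jittered restarts.
#' @return An object of class `fit_config`.
#' @export
fit_config <- function(alpha = 1, binning = grey_binning(), n_restarts = 8,
                       max_iter = 200, tol = 1e-10, seed = 1L) {
  stopifnot(inherits(binning, "grey_binning"))
  n_restarts <- as.integer(n_restarts)
  if (is.na(n_restarts) || n_restarts < 1L) {
    stop("`n_restarts` must be >= 1", call. = FALSE)
  }
  if (!is.numeric(tol) || tol <= 0) stop("`tol` must be positive", call. = FALSE)
  structure(list(alpha = alpha, binning = binning, n_restarts = n_restarts,
                 max_iter = as.integer(max_iter), tol = tol,
                 seed = as.integer(seed)),
            class = "fit_config")
}

# per-bin WLS weights x^alpha on G0 (0 outside); drops zero-count bins for
# alpha < 0 where the weight is undefined
.wls_weights <- function(counts, included, alpha) {
  g0 <- included
  if (alpha < 0) g0 <- g0 & counts > 0
  w <- numeric(length(counts))
  w[g0] <- if (alpha == 0) 1 else counts[g0]^alpha
  w
}

#' Weighted least-squares distance between histograms
#'
#' \deqn{S_\alpha = \sum_{n \in G_0} (x_n(Y) - x_n(\Theta))^2 \, x_n(Y)^\alpha}
#' The sum runs over the empirical histogram's included-bin set \eqn{G_0};
#' for `alpha < 0`, bins with zero empirical count are additionally dropped.
#'
#' @param empirical a [grey_histogram()].
#' @param theoretical a [theoretical_histogram()] on the same binning.
#' @param alpha weight exponent.
#' @return The non-negative distance \eqn{S_\alpha} (squared-count units);
#'   zero iff the histograms agree on \eqn{G_0}.
#' @examples
#' b <- grey_binning(0, 1, 3)
#' e <- grey_histogram(c(2, 0, 3), b)
#' t <- structure(list(expected = c(1, 0, 1), binning = b, q_total = 2),
#'                class = "theoretical_histogram")
#' wls_distance(e, t, 0)  # (2-1)^2 + 0 + (3-1)^2 = 5
#' wls_distance(e, t, 1)  # 1^2*2 + 0 + 2^2*3 = 14
#' @export
wls_distance <- function(empirical, theoretical, alpha) {
  stopifnot(inherits(empirical, "grey_histogram"),
            inherits(theoretical, "theoretical_histogram"))
  if (!.same_binning(empirical$binning, theoretical$binning)) {
    stop("histogram binnings do not match", call. = FALSE)
  }
  w <- .wls_weights(empirical$counts, empirical$included, alpha)
  sum(w * (empirical$counts - theoretical$expected)^2)
}

# parameter transform: optimization space -> mixture space
.par_to_theta <- function(p) {
  c(p[1], p[2], exp(p[3]), exp(p[4]), plogis(p[5]))
}

.theta_to_par <- function(th) {
  z <- min(max(th[5], 0.02), 0.98)   # keep logit finite for extreme starts
  c(th[1], th[2], log(th[3]), log(th[4]), qlogis(z))
}

# initialization candidates, deterministic in (x, seed):
#   - splits of the histogram at fixed mass quantiles, per-side moments
#   - the two largest well-separated smoothed modes
#   - seeded jitter around the median-split candidate
.fit_inits <- function(counts, binning, n_restarts, seed) {
  ctr <- bin_centers(binning)
  q <- sum(counts)
  sd_floor <- binning$width_hu / 2

  split_at <- function(frac) {
    k <- which(cumsum(counts) / q >= frac)[1]
    left <- seq_along(counts) <= k
    wl <- sum(counts[left]); wr <- sum(counts[!left])
    if (wl < 1 || wr < 1) return(NULL)
    ml <- sum(ctr[left] * counts[left]) / wl
    mr <- sum(ctr[!left] * counts[!left]) / wr
    sl <- sqrt(max(sum((ctr[left] - ml)^2 * counts[left]) / wl, sd_floor^2))
    sr <- sqrt(max(sum((ctr[!left] - mr)^2 * counts[!left]) / wr, sd_floor^2))
    c(ml, mr, sl, sr, wl / q)
  }

  mode_init <- function() {
    xs <- as.numeric(stats::filter(counts, rep(1 / 5, 5), sides = 2))
    xs[is.na(xs)] <- 0
    o <- order(xs, decreasing = TRUE)
    p1 <- o[1]
    p2 <- o[which(abs(o - p1) > 5)[1]]
    if (is.na(p2)) return(NULL)
    e1 <- min(ctr[p1], ctr[p2]); e2 <- max(ctr[p1], ctr[p2])
    m <- sum(ctr * counts) / q
    s <- sqrt(max(sum((ctr - m)^2 * counts) / q, sd_floor^2))
    zl <- sum(counts[ctr < (e1 + e2) / 2]) / q
    c(e1, e2, max(s / 2, sd_floor), max(s / 2, sd_floor),
      min(max(zl, 0.02), 0.98))
  }

  cands <- Filter(Negate(is.null),
                  c(lapply(c(0.5, 0.3, 0.7, 0.15, 0.85), split_at),
                    list(mode_init())))
  if (length(cands) == 0L) stop("histogram too degenerate to initialize",
                                call. = FALSE)
  if (length(cands) < n_restarts) {
    base <- cands[[1]]
    extra <- .with_seed(seed, {
      lapply(seq_len(n_restarts - length(cands)), function(i) {
        j <- base
        j[1:2] <- j[1:2] + rnorm(2, 0, 5 * binning$width_hu)
        j[3:4] <- j[3:4] * exp(rnorm(2, 0, 0.4))
        j[5] <- min(max(j[5] + rnorm(1, 0, 0.15), 0.02), 0.98)
        j
      })
    })
    cands <- c(cands, extra)
  }
  cands[seq_len(min(n_restarts, length(cands)))]
}

#' Fit the two-Gaussian mixture to a grey-value histogram
#'
#' The CFES estimation step: minimizes the WLS distance between the
#' empirical histogram and the model-expected histogram over
#' \eqn{\Theta = (E_F, E_M, S_F, S_M, z)}, using Levenberg-Marquardt least
#' squares with the analytic model Jacobian on transformed parameters, from
#' several deterministic starting points.  The best final objective wins
#' (ties broken by restart order); the result is deterministic given the
#' configuration seed.
#'
#' @param empirical a [grey_histogram()] with \eqn{Q > 0} and at least two
#'   occupied bins.
#' @param config a [fit_config()].
#' @return An object of class `cfes_fit` with fields `theta_star` (the
#'   fitted [mixture_params()]), `s_alpha` and `ln_s_alpha` (achieved WLS
#'   distance and its natural log), `t_fm` (threshold bin index, see
#'   [compute_threshold()]), `q_f` and `q_m` (estimated fat and muscle pixel
#'   counts, `q_f = z* Q`), `converged`, and `objective_trace` (final
#'   objective per restart).
#' @examples
#' th <- mixture_params(-80, 50, 10, 10, 0.3)
#' b <- grey_binning()
#' x <- theoretical_histogram(th, 2e5, b)
#' fit <- fit_cfes(grey_histogram(x$expected, b), fit_config(alpha = 1, binning = b))
#' fit$theta_star
#' @export
fit_cfes <- function(empirical, config = fit_config()) {
  stopifnot(inherits(empirical, "grey_histogram"),
            inherits(config, "fit_config"))
  x <- empirical$counts
  q <- empirical$q_total
  binning <- empirical$binning
  if (!.same_binning(binning, config$binning)) {
    stop("histogram and config binnings do not match", call. = FALSE)
  }
  if (q <= 0) stop("histogram is empty", call. = FALSE)
  if (sum(x > 0) < 2L) {
    stop("histogram needs at least two occupied bins", call. = FALSE)
  }

  w <- .wls_weights(x, empirical$included, config$alpha)
  sw <- sqrt(w)

  resid_fn <- function(p) {
    th <- .par_to_theta(p)
    sw * (x - q * .mix_masses_vec(th, .bb))
  }
  jac_fn <- function(p) {
    th <- .par_to_theta(p)
    J <- .mass_jacobian(th, binning)            # d bin-mass / d theta
    D <- c(1, 1, th[3], th[4], th[5] * (1 - th[5]))
    -sw * q * sweep(J, 2, D, `*`)
  }
  .bb <- .bin_bounds(binning)

  inits <- .fit_inits(x, binning, config$n_restarts, config$seed)
  trace <- rep(NA_real_, length(inits))
  fits <- vector("list", length(inits))
  for (i in seq_along(inits)) {
    # optimizer status chatter is muffled; convergence is reported via the
    # `converged` flag and the objective trace instead
    f <- tryCatch(
      withCallingHandlers(
        minpack.lm::nls.lm(
          par = .theta_to_par(inits[[i]]), fn = resid_fn, jac = jac_fn,
          control = minpack.lm::nls.lm.control(
            maxiter = config$max_iter, ftol = config$tol)),
        warning = function(w) invokeRestart("muffleWarning")),
      error = function(e) NULL)
    if (is.null(f)) next
    fits[[i]] <- f
    trace[i] <- f$deviance
  }
  if (all(is.na(trace))) {
    stop("all restarts failed to converge; objective trace: ",
         paste(format(trace), collapse = ", "), call. = FALSE)
  }
  best <- which.min(trace)                      # ties: lowest restart index
  fbest <- fits[[best]]
  thv <- .par_to_theta(fbest$par)
  theta_star <- mixture_params(thv[1], thv[2], thv[3], thv[4], thv[5])

  s_alpha <- wls_distance(
    empirical, theoretical_histogram(theta_star, q, binning), config$alpha)
  t_fm <- tryCatch(compute_threshold(theta_star, binning),
                   error = function(e) NA_integer_)

  structure(
    list(theta_star = theta_star,
         s_alpha = s_alpha,
         ln_s_alpha = log(s_alpha),
         t_fm = t_fm,
         q_f = theta_star$z * q,
         q_m = (1 - theta_star$z) * q,
         q_total = q,
         alpha = config$alpha,
         binning = binning,
         converged = fbest$info %in% 1:4,
         objective_trace = trace),
    class = "cfes_fit")
}

#' @export
print.cfes_fit <- function(x, ...) {
  t <- x$theta_star
  cat(sprintf(
    paste0("<cfes_fit> alpha = %g, %sconverged\n",
           "  Theta* : E_F = %.2f, E_M = %.2f, S_F = %.2f, S_M = %.2f HU, z = %.4f\n",
           "  S_alpha = %.6g (ln = %.3f), t_FM = bin %s, Q_F = %.0f of %g\n"),
    x$alpha, if (x$converged) "" else "NOT ",
    t$e_f, t$e_m, t$s_f, t$s_m, t$z,
    x$s_alpha, x$ln_s_alpha, format(x$t_fm), x$q_f, x$q_total))
  invisible(x)
}

#' Fat/muscle threshold of a fitted mixture
#'
#' The threshold bin \eqn{t_{FM}} that minimizes the expected number of
#' misclassified pixels under the fitted model when every pixel in a bin
#' below \eqn{t_{FM}} is labelled fat and every other masked pixel muscle.
#' This is the bin whose lower edge is closest to the crossing point of
#' \eqn{z f_F} and \eqn{(1-z) f_M}; it is found by brute-force scan over all
#' candidate bins, ties going to the lower bin.
#'
#' If the weighted densities do not cross strictly between \eqn{E_F} and
#' \eqn{E_M} (extreme \eqn{z}), the argmin is still returned but carries the
#' attribute `flagged = TRUE`.
#'
#' @param theta_star fitted [mixture_params()] with `e_f < e_m`.
#' @param binning a [grey_binning()].
#' @return Integer bin index in `1:(n_bins + 1)`; pixels with bin index
#'   `< t_fm` are labelled fat.  Attribute `flagged` marks degenerate cases.
#' @export
compute_threshold <- function(theta_star, binning) {
  .check_theta(theta_star)
  stopifnot(inherits(binning, "grey_binning"))
  if (theta_star$e_f >= theta_star$e_m) {
    stop("threshold requires e_f < e_m", call. = FALSE)
  }
  n <- binning$n_bins
  e <- bin_edges(binning)
  edges_t <- c(-Inf, e[2:n], Inf)               # lower edge of bin t, t = 1..n+1
  z <- theta_star$z
  miscl <- z * (1 - pnorm(edges_t, theta_star$e_f, theta_star$s_f)) +
    (1 - z) * pnorm(edges_t, theta_star$e_m, theta_star$s_m)
  t_fm <- which.min(miscl)                      # first minimum = lower bin
  edge <- edges_t[t_fm]
  flagged <- !is.finite(edge) || edge <= theta_star$e_f || edge >= theta_star$e_m
  if (flagged) {
    warning("weighted densities do not cross strictly between E_F and E_M; ",
            "threshold flagged", call. = FALSE)
  }
  structure(as.integer(t_fm), flagged = flagged)
}

#' Quasi-segmentation of a slice by a global threshold
#'
#' Labels every masked pixel by its histogram bin: bins below `t_fm` are
#' fat, the rest muscle; masked-out pixels are `LABEL_EXCLUDED`.
#'
#' @param image a [slice_image()].
#' @param t_fm threshold bin index from [compute_threshold()].
#' @param binning a [grey_binning()].
#' @return A [label_map()].
#' @export
quasi_segment <- function(image, t_fm, binning) {
  stopifnot(inherits(image, "slice_image"), inherits(binning, "grey_binning"))
  t_fm <- as.integer(t_fm)
  if (is.na(t_fm) || t_fm < 1L || t_fm > binning$n_bins + 1L) {
    stop("`t_fm` must be a bin index in 1:(n_bins + 1)", call. = FALSE)
  }
  labels <- matrix(LABEL_EXCLUDED, nrow(image$pixels), ncol(image$pixels))
  g <- image$pixels[image$mask]
  labels[image$mask] <- ifelse(bin_index(g, binning) < t_fm,
                               LABEL_FAT, LABEL_MUSCLE)
  label_map(labels)
}

#' Fat volume from a fat pixel count
#'
#' `q_f * pixel_area * slice_spacing`.  The spacing between slices (not the
#' nominal slice thickness) is the relevant third dimension of a pixel's
#' volume element.
#'
#' @param q_f fat pixel count (may be fractional, `z* Q`).
#' @param pixel_area in-plane pixel area in mm^2.
#' @param slice_spacing spacing between slices in mm.
#' @return Volume in mm^3.
#' @examples
#' fat_volume(1000, 1, 0.625)  # 625 mm^3
#' @export
fat_volume <- function(q_f, pixel_area, slice_spacing) {
  if (!is.numeric(q_f) || any(q_f < 0)) {
    stop("`q_f` must be non-negative", call. = FALSE)
  }
  if (pixel_area <= 0 || slice_spacing <= 0) {
    stop("`pixel_area` and `slice_spacing` must be positive", call. = FALSE)
  }
  q_f * pixel_area * slice_spacing
}
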