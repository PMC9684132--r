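# Reproducible experiment drivers: the Monte Carlo phantom sweep relating
# estimated separability tau* to the log WLS distance, the two-point
# boundary-line estimators used to bound misclassification scatterplots, and
# the tau*-vs-ln(S_alpha) regression.

#' Monte Carlo phantom sweep (the "umbrella" experiment)
#'
#' Generates seeded phantoms for every combination of fat ratio, component
#' SD and replicate, fits each with [fit_cfes()], and records the true and
#' estimated separability, the log WLS distance and the relative fat-ratio
#' error.  The sweep is fully deterministic given `base_seed`; per-image fit
#' failures are recorded as flagged rows and never abort the sweep.
#'
#' The `excluded` column marks rows with `s_true <= 5`, `s_true >= 100` or
#' `re_z >= 0.2` — the filter used when relating the sweep to the fat-ratio
#' error surface.
#'
#' @param z_values true fat ratios; each value becomes one series
#'   (`A`, `B`, ...).
#' @param s_grid component SDs in HU, default [default_s_grid()].
#' @param replicates phantoms per (z, S) cell.
#' @param alpha weight exponent used by the fits.
#' @param base_seed integer seed controlling phantoms and fits.
#' @param size phantom frame side length in pixels.
#' @param binning a [grey_binning()].
#' @param n_restarts multi-start count per fit.
#' @return Data frame with one row per phantom: `series`, `z_true`,
#'   `s_true`, `replicate`, `q_fm`, `tau_true`, `tau_star`, `z_star`,
#'   `ln_s_alpha`, `re_z`, `converged`, `fit_failed`, `excluded`.
#' @export
run_umbrella <- function(z_values = 0.3, s_grid = default_s_grid(),
                         replicates = 5, alpha = 1, base_seed = 1L,
                         size = 512, binning = grey_binning(),
                         n_restarts = 8) {
  if (length(z_values) == 0L || any(z_values <= 0 | z_values >= 1)) {
    stop("`z_values` must lie strictly in (0, 1)", call. = FALSE)
  }
  if (length(s_grid) == 0L || any(s_grid <= 0)) {
    stop("`s_grid` must be positive and non-empty", call. = FALSE)
  }
  rows <- vector("list", length(z_values) * length(s_grid) * replicates)
  i <- 0L
  for (zi in seq_along(z_values)) {
    z <- z_values[zi]
    for (s in s_grid) {
      for (r in seq_len(replicates)) {
        spec <- phantom_spec(mixture_params(-80, 50, s, s, z), size = size,
                             seed = derive_seed(base_seed, s, r, z))
        ph <- generate_phantom(spec)
        hist <- compute_histogram(ph$image, binning)
        q_fm <- hist$q_total
        tau_true <- separability_tau(spec$theta_true, q_fm)
        cfg <- fit_config(alpha = alpha, binning = binning,
                          n_restarts = n_restarts,
                          seed = derive_seed(base_seed + 1L, s, r, z))
        fit <- tryCatch(fit_cfes(hist, cfg), error = function(e) NULL)
        i <- i + 1L
        if (is.null(fit)) {
          rows[[i]] <- data.frame(
            series = LETTERS[zi], z_true = z, s_true = s, replicate = r,
            q_fm = q_fm, tau_true = tau_true, tau_star = NA_real_,
            z_star = NA_real_, ln_s_alpha = NA_real_, re_z = NA_real_,
            converged = FALSE, fit_failed = TRUE, excluded = TRUE)
          next
        }
        z_star <- fit$theta_star$z
        tau_star <- tryCatch(separability_tau(fit$theta_star, q_fm),
                             error = function(e) NA_real_)
        re_z <- relative_error_z(z, z_star)
        rows[[i]] <- data.frame(
          series = LETTERS[zi], z_true = z, s_true = s, replicate = r,
          q_fm = q_fm, tau_true = tau_true, tau_star = tau_star,
          z_star = z_star, ln_s_alpha = fit$ln_s_alpha, re_z = re_z,
          converged = fit$converged, fit_failed = FALSE,
          excluded = s <= 5 || s >= 100 || re_z >= 0.2)
      }
    }
  }
  do.call(rbind, rows)
}

#' Two-point boundary line
#'
#' The line through `(x0, y0)` and `(x1, y1)`, used to bound the upper edge
#' of a misclassification scatterplot: slope `(y1 - y0)/(x1 - x0)` and
#' intercept `y1 - slope * x1`.  When results are reported in two steps
#' (slope first, then intercept computed from the already-rounded slope),
#' set `slope_digits` to reproduce that convention.
#'
#' @param x0,y0,x1,y1 the two data points; `x0 != x1`.
#' @param slope_digits optional number of decimals the slope is rounded to
#'   before the intercept is computed; `NULL` (default) keeps full precision.
#' @return Named list with `slope` and `intercept`.
#' @examples
#' boundary_line(103.0, 21.35, 654.0, 0.0, slope_digits = 5)
#' @export
boundary_line <- function(x0, y0, x1, y1, slope_digits = NULL) {
  if (!all(is.finite(c(x0, y0, x1, y1)))) {
    stop("boundary points must be finite", call. = FALSE)
  }
  if (x0 == x1) stop("degenerate line: x0 == x1", call. = FALSE)
  slope <- (y1 - y0) / (x1 - x0)
  if (!is.null(slope_digits)) slope <- round(slope, slope_digits)
  list(slope = slope, intercept = y1 - slope * x1)
}

#' Simple regression of the log WLS distance on the separability
#'
#' Ordinary least-squares regression of per-scan mean
#' \eqn{\ln S_\alpha} on per-scan mean \eqn{\tau^*} (closed-form simple
#' regression; no iterative fitting).
#'
#' @param rows data frame of per-scan means.
#' @param tau_col,lns_col names of the predictor and response columns.
#' @return Named list with `slope`, `intercept`, `r_squared`, `p_value`.
#' @export
regress_lns_on_tau <- function(rows, tau_col = "tau_star",
                               lns_col = "ln_s_alpha") {
  stopifnot(is.data.frame(rows), tau_col %in% names(rows),
            lns_col %in% names(rows))
  d <- rows[is.finite(rows[[tau_col]]) & is.finite(rows[[lns_col]]), ]
  if (nrow(d) < 3L) stop("need at least 3 rows", call. = FALSE)
  x <- d[[tau_col]]; y <- d[[lns_col]]
  if (stats::var(x) == 0) {
    stop("degenerate regression: predictor has zero variance", call. = FALSE)
  }
  fit <- lm(y ~ x)
  sm <- summary(fit)
  list(slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
       r_squared = sm$r.squared,
       p_value = unname(sm$coefficients[2, 4]))
}

#' Fit and score a stack of slices
#'
#' Runs the full estimation chain (histogram, mixture fit, threshold,
#' quasi-segmentation) on every slice of a scan and aggregates the quality
#' measures: per-slice \eqn{\tau^*}, \eqn{\ln S_\alpha} and verdict
#' \eqn{d}, and the per-scan means \eqn{\mu(\tau^*)}, \eqn{\mu(\ln S_\alpha)}
#' and rate \eqn{D}.  Slices that fail to fit are logged, skipped and
#' counted.
#'
#' @param images list of [slice_image()]s (one scan's slices).
#' @param config a [fit_config()].
#' @param reference optional: a list of ground-truth [label_map()]s (one per
#'   slice), or a data frame of observer verdicts as returned by
#'   [read_verdict_manifest()] whose `id` matches the slice index.
#' @param epsilon disagreement tolerance passed to [misclassification_d()].
#' @return List with `slices` (per-slice data frame: `slice`, `tau_star`,
#'   `z_star`, `ln_s_alpha`, `t_fm`, `d`, `re_z`) and `summary` (named list:
#'   `n_slices`, `n_failed`, `mu_tau`, `mu_ln_s`, `D`).
#' @export
scan_pipeline <- function(images, config = fit_config(), reference = NULL,
                          epsilon = 0.02) {
  if (!is.list(images) || length(images) == 0L) {
    stop("`images` must be a non-empty list of slices", call. = FALSE)
  }
  verdicts <- NULL
  ref_maps <- NULL
  if (is.data.frame(reference)) {
    verdicts <- setNames(reference$verdict, reference$id)
  } else if (!is.null(reference)) {
    if (length(reference) != length(images)) {
      stop("`reference` must supply one label map per slice", call. = FALSE)
    }
    ref_maps <- reference
  }
  rows <- vector("list", length(images))
  n_failed <- 0L
  for (l in seq_along(images)) {
    img <- images[[l]]
    row <- tryCatch({
      hist <- compute_histogram(img, config$binning)
      fit <- fit_cfes(hist, config)
      d <- NA_integer_
      re_z <- NA_real_
      if (!is.null(verdicts)) {
        d <- unname(verdicts[as.character(l)])
      } else if (!is.null(ref_maps)) {
        seg <- quasi_segment(img, fit$t_fm, config$binning)
        d <- misclassification_d(seg, ref_maps[[l]], epsilon)
        ref_l <- ref_maps[[l]]$labels
        z_true <- sum(ref_l == LABEL_FAT) / sum(ref_l != LABEL_EXCLUDED)
        if (z_true > 0) re_z <- relative_error_z(z_true, fit$theta_star$z)
      }
      data.frame(slice = l,
                 tau_star = separability_tau(fit$theta_star, hist$q_total),
                 z_star = fit$theta_star$z,
                 ln_s_alpha = fit$ln_s_alpha,
                 t_fm = as.integer(fit$t_fm), d = d, re_z = re_z)
    }, error = function(e) {
      message(sprintf("slice %d skipped: %s", l, conditionMessage(e)))
      NULL
    })
    if (is.null(row)) n_failed <- n_failed + 1L else rows[[l]] <- row
  }
  slices <- do.call(rbind, rows)
  if (is.null(slices)) stop("no slice could be processed", call. = FALSE)
  summary <- list(
    n_slices = length(images), n_failed = n_failed,
    mu_tau = mean(slices$tau_star), mu_ln_s = mean(slices$ln_s_alpha),
    D = if (all(is.na(slices$d))) NA_real_
        else misclassification_rate(slices$d[!is.na(slices$d)]))
  list(slices = slices, summary = summary)
}
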