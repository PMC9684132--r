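# Seeded two-material phantom simulator.
#
# The phantom emulates an abdominal CT slice at histogram level: a muscle
# disk on an air background with an interior fat annulus, each tissue pixel
# drawn independently from its Normal grey-value distribution.  The annulus
# is grown pixel-by-pixel around a target ring radius so that the fat pixel
# count matches round(z * Q) exactly; the exact layout is irrelevant for the
# histogram-based estimator, which never looks at pixel positions.

#' Phantom specification
#'
#' Describes a synthetic two-material slice: the true mixture parameters
#' \eqn{\Theta^+ = (E_F^+, E_M^+, S_F^+, S_M^+, z^+)}, the frame size, the
#' concentric-disk geometry and the random seed.
#'
#' @param theta_true a [mixture_params()] with the true component means/SDs
#'   (HU) and the true fat ratio \eqn{z^+}.
#' @param size image side length in pixels (at least 64); the frame is
#'   `size` x `size`.
#' @param geometry list with `body_radius_frac` (radius of the muscle disk as
#'   a fraction of `size`) and `ring_radius_frac` (central radius of the fat
#'   annulus).  The annulus thickness is solved so the fat pixel count equals
#'   `round(z * Q)` exactly.
#' @param seed integer random seed; identical specs generate bit-identical
#'   phantoms.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(theta_true, size = 512,
                         geometry = list(body_radius_frac = 0.45,
                                         ring_radius_frac = 0.28),
                         seed = 1L) {
  .check_theta(theta_true)
  size <- as.integer(size)
  if (is.na(size) || size < 64L) {
    stop("`size` must be an integer >= 64", call. = FALSE)
  }
  if (!is.list(geometry) || is.null(geometry$body_radius_frac) ||
      is.null(geometry$ring_radius_frac)) {
    stop("`geometry` needs `body_radius_frac` and `ring_radius_frac`",
         call. = FALSE)
  }
  if (geometry$body_radius_frac <= 0 || geometry$body_radius_frac > 0.5) {
    stop("`body_radius_frac` must lie in (0, 0.5]", call. = FALSE)
  }
  seed <- as.integer(seed)
  if (is.na(seed)) stop("`seed` must be an integer", call. = FALSE)
  structure(list(theta_true = theta_true, size = size, geometry = geometry,
                 seed = seed),
            class = "phantom_spec")
}

#' @export
print.phantom_spec <- function(x, ...) {
  t <- x$theta_true
  cat(sprintf(
    "<phantom_spec> %dx%d, E_F=%g E_M=%g S_F=%g S_M=%g z=%g, seed=%d\n",
    x$size, x$size, t$e_f, t$e_m, t$s_f, t$s_m, t$z, x$seed))
  invisible(x)
}

# distance of every pixel center to the frame center
.pixel_dist <- function(size) {
  ctr <- (size + 1) / 2
  d <- (seq_len(size) - ctr)^2
  sqrt(outer(d, d, `+`))
}

#' Masked pixel count of the default phantom geometry
#'
#' Number of body (fat-or-muscle) pixels \eqn{Q_{FM}} of a concentric-disk
#' phantom of the given frame size.  This is the pixel count behind all
#' phantom-scale sensitivity computations and is recorded explicitly because
#' it depends on the geometry, not only on the frame size.
#'
#' @param size frame side length in pixels.
#' @param body_radius_frac muscle-disk radius as fraction of `size`.
#' @return Integer pixel count.
#' @examples
#' phantom_mask_count(512)
#' @export
phantom_mask_count <- function(size = 512, body_radius_frac = 0.45) {
  sum(.pixel_dist(size) <= body_radius_frac * size)
}

# run `expr` under a fixed seed without disturbing the caller's RNG stream
.with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# splittable per-item seed: a fixed linear-congruential style hash of the
# base seed and the item coordinates (S in milli-HU, replicate, z in 1e-6),
# reduced modulo a Mersenne prime so it stays a valid 32-bit seed
derive_seed <- function(base_seed, s, replicate, z) {
  h <- (69069 * (as.numeric(base_seed) %% 2147483647) +
          40503 * round(1000 * s) +
          10007 * replicate +
          313 * round(1e6 * z)) %% 2147483647
  as.integer(h) + 1L
}

#' Generate a synthetic two-material CT slice
#'
#' Builds the phantom raster described by a [phantom_spec()]: air background
#' (sentinel -1000 HU, masked out), a muscle disk, and an interior fat
#' annulus whose pixel count equals `round(z * Q)` exactly (fat pixels are
#' the `K` masked pixels whose distance to the center is closest to the ring
#' radius, ties broken in column-major pixel order).  Each fat pixel's value
#' is drawn `Normal(E_F, S_F)`, each muscle pixel `Normal(E_M, S_M)`,
#' independently.  The same spec always generates bit-identical output.
#'
#' @param spec a [phantom_spec()].
#' @return A list with components `image` (a [slice_image()], with the spec
#'   attached as provenance) and `labels` (the ground-truth [label_map()]).
#' @examples
#' ph <- generate_phantom(phantom_spec(mixture_params(-80, 50, 10, 10, 0.3),
#'                                     size = 64))
#' mean(ph$labels$labels[ph$image$mask] == LABEL_FAT)
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  size <- spec$size
  th <- spec$theta_true
  d <- .pixel_dist(size)
  mask <- d <= spec$geometry$body_radius_frac * size
  q_fm <- sum(mask)
  k_fat <- round(th$z * q_fm)
  if (k_fat < 0 || k_fat > q_fm) {
    stop("geometry cannot realize the requested fat fraction", call. = FALSE)
  }

  ring_r <- spec$geometry$ring_radius_frac * size
  body_idx <- which(mask)                        # column-major, deterministic
  ord <- order(abs(d[body_idx] - ring_r), body_idx)
  fat_idx <- body_idx[ord[seq_len(k_fat)]]
  muscle_idx <- setdiff(body_idx, fat_idx)

  labels <- matrix(LABEL_EXCLUDED, size, size)
  labels[muscle_idx] <- LABEL_MUSCLE
  labels[fat_idx] <- LABEL_FAT

  pixels <- matrix(-1000, size, size)
  .with_seed(spec$seed, {
    pixels[fat_idx] <- rnorm(k_fat, th$e_f, th$s_f)
    pixels[muscle_idx] <- rnorm(q_fm - k_fat, th$e_m, th$s_m)
  })

  list(image = slice_image(pixels, mask, provenance = spec),
       labels = label_map(labels))
}

#' Generate a seeded series of phantoms over a grid of component SDs
#'
#' One phantom per (S, replicate) combination with `S = S_F = S_M` running
#' over `s_grid`, fixed component means (defaults `E_F = -80` HU,
#' `E_M = 50` HU) and fixed fat ratio `z_value`.  Per-item seeds are derived
#' deterministically from `base_seed` via a splittable hash of
#' (S, replicate, z), so any sub-experiment can be regenerated in isolation.
#'
#' @param z_value true fat ratio shared by all phantoms.
#' @param s_grid vector of component SDs in HU (positive, non-empty).
#' @param replicates number of phantoms per S value (at least 1).
#' @param base_seed integer base seed.
#' @param size frame side length in pixels.
#' @param e_f,e_m component means in HU.
#' @param geometry phantom geometry, see [phantom_spec()].
#' @return A list of length `length(s_grid) * replicates`; each element is
#'   the result of [generate_phantom()] plus its `spec`.
#' @export
phantom_series <- function(z_value, s_grid, replicates, base_seed,
                           size = 512, e_f = -80, e_m = 50,
                           geometry = list(body_radius_frac = 0.45,
                                           ring_radius_frac = 0.28)) {
  if (length(s_grid) == 0L || !is.numeric(s_grid) || any(s_grid <= 0)) {
    stop("`s_grid` must be a non-empty vector of positive SDs", call. = FALSE)
  }
  if (!is.numeric(replicates) || length(replicates) != 1L || replicates < 1) {
    stop("`replicates` must be >= 1", call. = FALSE)
  }
  out <- vector("list", length(s_grid) * replicates)
  i <- 0L
  for (s in s_grid) {
    for (r in seq_len(replicates)) {
      spec <- phantom_spec(mixture_params(e_f, e_m, s, s, z_value),
                           size = size, geometry = geometry,
                           seed = derive_seed(base_seed, s, r, z_value))
      ph <- generate_phantom(spec)
      i <- i + 1L
      out[[i]] <- list(image = ph$image, labels = ph$labels, spec = spec)
    }
  }
  out
}

#' The component-SD grid of the phantom study
#'
#' The 20 values of `S = S_F = S_M` (HU) over which the Monte Carlo phantom
#' series are generated.
#'
#' @return Numeric vector of 20 SD values in HU.
#' @export
default_s_grid <- function() {
  c(10, 12, 14, 15, 17, 20, 25, 30, 35, 40,
    45, 55, 60, 70, 80, 90, 100, 150, 200, 250)
}
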