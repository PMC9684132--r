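test_that("histogram extraction counts masked pixels per bin", {
  # a constant 512x512 slice puts all 262,144 pixels into the water bin
  img <- slice_image(matrix(0, 512, 512))
  h <- compute_histogram(img, default_binning)
  expect_identical(h$counts[129], 262144)
  expect_identical(sum(h$counts), 262144)

  img2 <- slice_image(matrix(c(-80, -80, 50, 50), 2, 2))
  h2 <- compute_histogram(img2, default_binning)
  expect_identical(h2$counts[c(109, 141)], c(2, 2))
  expect_identical(sum(h2$counts), 4)

  # conservation under an arbitrary mask
  withr::with_seed(4, {
    px <- matrix(rnorm(900, 0, 200), 30, 30)
    mk <- matrix(runif(900) < 0.6, 30, 30)
  })
  h3 <- compute_histogram(slice_image(px, mk), default_binning)
  expect_equal(sum(h3$counts), sum(mk))
  expect_error(compute_histogram(slice_image(px, mk & FALSE), default_binning),
               "masked-in")
})

test_that("WLS distance follows its defining sum", {
  b3 <- grey_binning(0, 1, 3)
  e <- grey_histogram(c(2, 0, 3), b3)
  t1 <- theoretical_histogram(mixture_params(0.2, 2.2, 1, 1, 0.5), 2, b3)
  t1$expected <- c(1, 0, 1)   # fixed reference values for hand arithmetic
  expect_equal(wls_distance(e, t1, 0), 5)       # (2-1)^2 + 0 + (3-1)^2
  expect_equal(wls_distance(e, t1, 1), 14)      # 1^2*2 + 0 + 2^2*3
  # zero-count bins drop out of G0 for negative alpha
  t2 <- t1; t2$expected <- c(1, 5, 1)
  expect_equal(wls_distance(e, t2, -1), 1 / 2 + 4 / 3)
  # identical histograms have zero distance
  t3 <- t1; t3$expected <- c(2, 0, 3)
  expect_equal(wls_distance(e, t3, 1), 0)
  # binning mismatch rejected
  e4 <- grey_histogram(c(2, 0, 3, 0), grey_binning(0, 1, 4))
  expect_error(wls_distance(e4, t1, 1), "binning")
})

test_that("fitting an exact model histogram recovers the parameters", {
  th <- mixture_params(-80, 50, 10, 10, 0.3)
  xt <- theoretical_histogram(th, 2e5, default_binning)
  fit <- fit_cfes(grey_histogram(xt$expected, default_binning), quick_config())
  rel <- abs(unlist(fit$theta_star) - unlist(th)) /
    pmax(abs(unlist(th)), 1e-12)
  expect_lt(max(rel), 1e-3)
  expect_true(fit$converged)
  expect_equal(fit$q_f + fit$q_m, 2e5)
  expect_lt(fit$s_alpha, 1e-6)
})

test_that("phantom fit at low component SD recovers z tightly", {
  ph <- small_phantom(10, z = 0.3, size = 256, seed = 21)
  h <- compute_histogram(ph$image, default_binning)
  fit <- fit_cfes(h, quick_config(seed = 22))
  expect_lt(relative_error_z(0.3, fit$theta_star$z), 0.02)
})

test_that("fit results are invariant under a common HU shift", {
  th <- mixture_params(-80, 50, 18, 22, 0.35)
  h <- multinomial_hist(th, 5e4, default_binning, seed = 31)
  f0 <- fit_cfes(h, quick_config(seed = 32))
  shifted <- grey_binning(default_binning$origin_hu + 100,
                          default_binning$width_hu, default_binning$n_bins)
  hs <- grey_histogram(h$counts, shifted)   # same counts, shifted grey axis
  fs <- fit_cfes(hs, quick_config(binning = shifted, seed = 32))
  expect_equal(fs$theta_star$z, f0$theta_star$z, tolerance = 1e-6)
  expect_equal(fs$s_alpha, f0$s_alpha, tolerance = 1e-6)
  expect_equal(fs$theta_star$e_f - 100, f0$theta_star$e_f, tolerance = 1e-4)
})

test_that("the optimizer never does worse than the generating parameters", {
  withr::with_seed(41, {
    for (i in 1:50) {
      e1 <- runif(1, -200, 0)
      th <- mixture_params(e1, e1 + runif(1, 60, 250),
                           runif(1, 8, 40), runif(1, 8, 40),
                           runif(1, 0.1, 0.9))
      h <- multinomial_hist(th, 2e4, default_binning,
                            seed = sample.int(1e6, 1))
      fit <- fit_cfes(h, quick_config(seed = i, n_restarts = 5))
      s_truth <- wls_distance(
        h, theoretical_histogram(th, h$q_total, default_binning), 1)
      expect_lte(fit$s_alpha, s_truth * (1 + 1e-6) + 1e-6)
    }
  })
})

test_that("a dense grid search cannot beat the optimizer on tiny histograms", {
  th <- mixture_params(2.5, 5.5, 0.8, 0.8, 0.4)
  h <- multinomial_hist(th, 500, bin8, seed = 51)
  expect_lte(sum(h$counts > 0), 8L)
  fit <- fit_cfes(h, quick_config(binning = bin8, seed = 52))

  # independent coarse 5-D grid evaluation of the same objective
  obj <- function(ef, em, sf, sm, z) {
    p <- z * (pnorm(1:8, ef, sf) - pnorm(0:7, ef, sf)) +
      (1 - z) * (pnorm(1:8, em, sm) - pnorm(0:7, em, sm))
    p[1] <- p[1] + z * pnorm(0, ef, sf) + (1 - z) * pnorm(0, em, sm)
    p[8] <- p[8] + z * pnorm(8, ef, sf, lower.tail = FALSE) +
      (1 - z) * pnorm(8, em, sm, lower.tail = FALSE)
    sum((h$counts - 500 * p)^2 * h$counts)
  }
  grid <- expand.grid(ef = seq(1, 4, 0.5), em = seq(4.5, 7, 0.5),
                      sf = seq(0.4, 1.6, 0.3), sm = seq(0.4, 1.6, 0.3),
                      z = seq(0.1, 0.9, 0.1))
  grid_min <- min(mapply(obj, grid$ef, grid$em, grid$sf, grid$sm, grid$z))
  expect_gte(grid_min, fit$s_alpha - 0.01 * max(fit$s_alpha, 1))
})

test_that("the threshold minimizes expected misclassification", {
  b <- grey_binning(-128, 1, 256)
  miscl_at <- function(edge, th) {
    th$z * pnorm(edge, th$e_f, th$s_f, lower.tail = FALSE) +
      (1 - th$z) * pnorm(edge, th$e_m, th$s_m)
  }
  edges_t <- c(-Inf, bin_edges(b)[2:256], Inf)

  th5 <- mixture_params(-80, 50, 10, 10, 0.5)
  t5 <- compute_threshold(th5, b)
  # symmetric case: optimal edge is the midpoint of the means
  expect_equal(edges_t[t5], (-80 + 50) / 2)
  # brute-force oracle over every candidate edge
  expect_equal(miscl_at(edges_t[t5], th5), min(miscl_at(edges_t, th5)))

  th3 <- mixture_params(-80, 50, 10, 10, 0.3)
  t3 <- compute_threshold(th3, b)
  expect_lt(t3, t5)   # lower fat share pulls the threshold toward E_F
  expect_equal(miscl_at(edges_t[t3], th3), min(miscl_at(edges_t, th3)))

  # degenerate fat share: argmin path with warning flag
  th0 <- mixture_params(-80, 50, 10, 10, 0)
  expect_warning(t0 <- compute_threshold(th0, b), "flagged")
  expect_true(attr(t0, "flagged"))
  expect_error(compute_threshold(mixture_params(-80, -80, 10, 10, 0.5), b),
               "e_f < e_m")
})

test_that("quasi-segmentation labels masked pixels by their bin", {
  img <- slice_image(matrix(c(-80, -80, 50, 50), 2, 2))
  seg <- quasi_segment(img, 129L, default_binning)   # threshold at 0 HU
  expect_identical(sum(seg$labels == LABEL_FAT), 2L)
  expect_identical(sum(seg$labels == LABEL_MUSCLE), 2L)

  # threshold above every occupied bin: everything is fat
  seg_all <- quasi_segment(img, 257L, default_binning)
  expect_identical(sum(seg_all$labels == LABEL_FAT), 4L)

  # conservation with a mask
  ph <- small_phantom(20, size = 128)
  segp <- quasi_segment(ph$image, 125L, default_binning)
  expect_identical(sum(segp$labels != LABEL_EXCLUDED), sum(ph$image$mask))
  expect_error(quasi_segment(img, 0L, default_binning), "bin index")
})

test_that("fat volume is pixel count times voxel volume", {
  expect_equal(fat_volume(1000, 1, 0.625), 625)
  expect_equal(fat_volume(0, 1, 0.625), 0)
  expect_equal(fat_volume(100, 0.5, 3.00), 150)
  expect_error(fat_volume(100, 1, 0), "positive")
  expect_error(fat_volume(-1, 1, 1), "non-negative")
})
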