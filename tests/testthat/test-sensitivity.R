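test_that("model Jacobian columns conserve mass and reflect symmetry", {
  th <- mixture_params(-80, 50, 30, 45, 0.35)
  j <- model_jacobian(th, 1e5, default_binning)
  expect_identical(dim(j), c(256L, 5L))
  expect_lt(max(abs(colSums(j))), 1e-7)     # total count is theta-independent

  # indistinguishable components: z has no effect
  th_eq <- mixture_params(-10, -10, 25, 25, 0.4)
  j_eq <- model_jacobian(th_eq, 1e5, default_binning)
  expect_lt(max(abs(j_eq[, "z"])), 1e-12)
})

test_that("model Jacobian agrees with central finite differences", {
  withr::with_seed(71, {
    for (i in 1:3) {
      th <- mixture_params(runif(1, -150, -20), runif(1, 0, 150),
                           runif(1, 10, 60), runif(1, 10, 60),
                           runif(1, 0.15, 0.85))
      q <- 1e5
      j <- model_jacobian(th, q, default_binning)
      step <- 1e-5
      v <- unlist(th)
      for (k in 1:5) {
        hp <- v; hm <- v
        hp[k] <- hp[k] + step
        hm[k] <- hm[k] - step
        xp <- theoretical_histogram(do.call(mixture_params, as.list(hp)),
                                    q, default_binning)$expected
        xm <- theoretical_histogram(do.call(mixture_params, as.list(hm)),
                                    q, default_binning)$expected
        fd <- (xp - xm) / (2 * step)
        big <- abs(j[, k]) > 1e-8 * q
        expect_lt(max(abs(fd[big] - j[big, k]) / abs(j[big, k])), 1e-4)
      }
    }
  })
})

test_that("histogram covariance is multinomial", {
  th <- mixture_params(-80, 50, 40, 40, 0.3)
  v <- histogram_covariance(th, 1e4, default_binning)
  expect_lt(max(abs(rowSums(v))), 1e-7)
  expect_equal(v, t(v))

  # all mass in a single bin: no variability at all
  off <- mixture_params(1e4, 2e4, 1, 1, 0.3)   # far above the binning range
  v0 <- histogram_covariance(off, 1e4, default_binning)
  expect_lt(max(abs(v0)), 1e-9)
})

test_that("multinomial covariance matches simulated histograms", {
  th <- mixture_params(2.5, 5.5, 1.2, 1.2, 0.4)
  q <- 500
  v <- histogram_covariance(th, q, bin8)
  p <- theoretical_histogram(th, 1, bin8)$expected
  draws <- withr::with_seed(81, stats::rmultinom(10000, q, p))
  emp <- stats::cov(t(draws)) * (10000 - 1) / 10000
  se <- sqrt((outer(diag(v), diag(v)) + v^2) / 10000)
  expect_true(all(abs(emp - v) <= 5 * se + 1e-9))
})

test_that("sandwich covariance obeys its algebraic identities", {
  withr::with_seed(91, {
    j <- qr.Q(qr(matrix(rnorm(100), 20, 5)))   # orthonormal columns
  })
  colnames(j) <- c("e_f", "e_m", "s_f", "s_m", "z")
  v <- estimator_covariance(j, diag(20))
  expect_equal(unclass(v), diag(5), ignore_attr = TRUE, tolerance = 1e-10)

  # scaling the input covariance by 4 doubles every standard deviation
  th <- mixture_params(-80, 50, 20, 20, 0.3)
  jm <- model_jacobian(th, 1e5, default_binning)
  sig <- histogram_covariance(th, 1e5, default_binning)
  v1 <- estimator_covariance(jm, sig)
  v4 <- estimator_covariance(jm, 4 * sig)
  expect_equal(sqrt(v4["z", "z"]), 2 * sqrt(v1["z", "z"]), tolerance = 1e-10)

  # rank deficiency falls back to the pseudo-inverse with a warning
  jd <- cbind(jm[, 1], jm[, 1], jm[, 3:5])
  colnames(jd) <- colnames(jm)
  expect_warning(vd <- estimator_covariance(jd, sig), "singular")
  expect_true(attr(vd, "near_singular"))
})

test_that("analytic S(z*) matches a Monte Carlo of multinomial histograms", {
  # moderate overlap, LS weights (alpha = 0): the linearization is accurate
  th <- mixture_params(-80, 50, 40, 40, 0.3)
  q <- 20000
  analytic <- z_std_curve(40, z = 0.3, q_total = q)$z_std
  zs <- vapply(1:150, function(r) {
    h <- multinomial_hist(th, q, default_binning, seed = 9000 + r)
    fit_cfes(h, quick_config(alpha = 0, seed = r, n_restarts = 4))$theta_star$z
  }, numeric(1))
  expect_lt(abs(sd(zs) - analytic) / analytic, 0.25)
})

test_that("S(z*) grows steeply with component overlap", {
  grid <- seq(20, 130, by = 5)
  curve <- z_std_curve(grid)
  expect_true(all(diff(curve$z_std) > 0))
  # growth spans orders of magnitude over the grid: a linear increase in the
  # component SD multiplies the estimator dispersion a few hundredfold
  expect_gt(curve$z_std[curve$s == 130] / curve$z_std[curve$s == 20], 100)

  # translation invariance: shifting means and binning together
  b2 <- grey_binning(default_binning$origin_hu + 100, 4, 256)
  shifted <- z_std_curve(grid, e_f = 20, e_m = 150, binning = b2)
  expect_equal(shifted$z_std, curve$z_std, tolerance = 1e-10)

  # the true fat ratio has little influence on the curve
  c5 <- z_std_curve(grid, z = 0.5)
  expect_lt(max(abs(c5$z_std - curve$z_std) / curve$z_std), 0.15)
})
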