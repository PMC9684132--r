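# shared fixtures, all generated in code

default_binning <- grey_binning()

# a small 8-bin binning on [0, 8) HU for hand-checkable cases
bin8 <- grey_binning(0, 1, 8)

# draw an empirical histogram from the multinomial model itself
# (stochastically independent pixels with random material assignment)
multinomial_hist <- function(theta, q_total, binning, seed) {
  p <- theoretical_histogram(theta, 1, binning)$expected
  counts <- withr::with_seed(seed, as.vector(stats::rmultinom(1, q_total, p)))
  grey_histogram(counts, binning)
}

# random valid mixture parameters with separated components
random_theta <- function() {
  e <- sort(stats::runif(2, -300, 300))
  mixture_params(e[1], e[2], stats::runif(1, 0.5, 250),
                 stats::runif(1, 0.5, 250), stats::runif(1))
}

quick_config <- function(alpha = 1, binning = default_binning, seed = 1L,
                         n_restarts = 6) {
  fit_config(alpha = alpha, binning = binning, n_restarts = n_restarts,
             seed = seed)
}

small_phantom <- function(s, z = 0.3, size = 256, seed = 1L) {
  generate_phantom(phantom_spec(mixture_params(-80, 50, s, s, z),
                                size = size, seed = seed))
}
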