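test_that("approximate entropy matches a brute-force template scan", {
  set.seed(21)
  x <- rnorm(200)
  r_abs <- 0.2 * sd(x)
  expect_equal(approximate_entropy(x, m = 2, r = 0.2),
               apen_oracle(x, 2, r_abs), tolerance = 1e-12)
  x2 <- runif(120)
  expect_equal(approximate_entropy(x2, m = 3, r = 0.15),
               apen_oracle(x2, 3, 0.15 * sd(x2)), tolerance = 1e-12)
})

test_that("approximate entropy ranks regularity correctly", {
  expect_equal(approximate_entropy(rep(1.5, 100)), 0)
  for (s in 1:20) {
    sine <- fixture_signal("sine", 1000, f = 7 + s / 10, fs = 200)
    noise <- fixture_signal("white_noise", 1000, seed = s)
    expect_lt(approximate_entropy(sine), approximate_entropy(noise))
  }
  expect_error(approximate_entropy(rnorm(100), r = 0), "positive")
})

test_that("C0 complexity isolates the stochastic component", {
  tone <- fixture_signal("sine", 600, f = 10, fs = 200)  # integer cycles
  expect_lt(c0_complexity(tone), 0.05)
  for (s in 1:20)
    expect_gt(c0_complexity(fixture_signal("white_noise", 512, seed = s)), 0.5)
  set.seed(9)
  for (s in 1:10) {
    v <- c0_complexity(rnorm(128) + fixture_signal("sine", 128, f = 10, fs = 200))
    expect_gte(v, 0); expect_lte(v, 1)
  }
  expect_error(c0_complexity(rep(0, 64)), "zero-power")
})

test_that("correlation dimension recovers manifold dimensions", {
  # 1-D orbit: sine embedded at quarter-period delay
  s <- fixture_signal("sine", 2000, f = 5.07, fs = 200)
  expect_equal(as.numeric(correlation_dimension(s, m_range = 2, tau = 10)),
               1, tolerance = 0.15)
  expect_error(correlation_dimension(rep(1, 600)), "degenerate")
  expect_warning(correlation_dimension(rnorm(300)), "low-confidence")
})

test_that("correlation dimension of noise grows with m without saturating", {
  x <- fixture_signal("white_noise", 1500, seed = 33)
  ds <- vapply(2:6, function(m)
    as.numeric(correlation_dimension(x, m_range = m)), numeric(1))
  expect_true(all(diff(ds) > 0.3))
  full <- correlation_dimension(x, m_range = 2:6)
  expect_false(attr(full, "saturated"))
})

test_that("K2 entropy vanishes for periodic signals and is positive for chaos", {
  s <- fixture_signal("sine", 2000, f = 5.07, fs = 200)
  expect_lt(kolmogorov_entropy(s, m = 2, tau = 10), 0.05)
  x <- fixture_signal("logistic_map", 5000, r = 4)
  k2 <- kolmogorov_entropy(x, m = 2, tau = 1)
  expect_gt(k2, 0.5); expect_lt(k2, 0.9)
  # rate nonnegativity across fixtures
  for (fx in list(s, x, fixture_signal("white_noise", 1000, seed = 2)))
    expect_gte(kolmogorov_entropy(fx), 0)
})

test_that("the Lyapunov estimator recovers ln 2 for the r = 4 logistic map", {
  x <- fixture_signal("logistic_map", 5000, r = 4)
  lam <- lyapunov_exponent(x, m = 2, tau = 1)
  expect_equal(as.numeric(lam), log(2), tolerance = 0.1 * log(2))
  # amplitude scaling leaves the estimate unchanged
  expect_equal(as.numeric(lyapunov_exponent(250 * x, m = 2, tau = 1)),
               as.numeric(lam), tolerance = 1e-6)
})

test_that("non-chaotic signals have (near-)zero Lyapunov estimates", {
  for (s in 1:10) {
    set.seed(s)
    sine <- fixture_signal("sine", 2000, f = 4 + s / 3, fs = 200,
                           phase = runif(1, 0, 2 * pi))
    expect_lte(lyapunov_exponent(sine), 0.02)
  }
})

test_that("permutation entropy spans [0, 1] between regular and random", {
  expect_equal(permutation_entropy(1:1000), 0)
  expect_equal(permutation_entropy(seq(2, 5, length.out = 300), m = 4), 0)
  set.seed(5)
  expect_equal(permutation_entropy(runif(1e5), m = 3), 1, tolerance = 0.01)
  expect_error(permutation_entropy(rnorm(50), m = 1), "m must be")
})

test_that("permutation entropy equals exhaustive pattern counting", {
  set.seed(11)
  x <- sample.int(10, 50, replace = TRUE)   # integer data with ties
  expect_equal(permutation_entropy(x, m = 3), pe_oracle(x, 3),
               tolerance = 1e-14)
  y <- rnorm(60)
  expect_equal(permutation_entropy(y, m = 4, tau = 2), pe_oracle(y, 4, 2),
               tolerance = 1e-14)
})

test_that("SVD entropy separates low-rank from isotropic trajectories", {
  tone <- 2 + fixture_signal("sine", 500, f = 10, fs = 200)
  # rank-2 trajectory: the analytic floor is log(2)/log(10) ~ 0.301
  expect_lt(svd_entropy(tone, m = 10), 0.32)
  for (s in 1:20)
    expect_gt(svd_entropy(fixture_signal("white_noise", 500, seed = s),
                          m = 10), 0.8)
  expect_equal(svd_entropy(rep(3, 100)), 0)
  set.seed(6)
  v <- svd_entropy(rnorm(300))
  expect_gte(v, 0); expect_lte(v, 1)
})

test_that("SVD entropy matches a naive trajectory-matrix computation", {
  set.seed(12)
  x <- rnorm(150)
  expect_equal(svd_entropy(x, m = 12), svdent_oracle(x, 12), tolerance = 1e-10)
})

test_that("Shannon entropy follows the histogram definition", {
  # samples filling K bins uniformly -> ln K
  x <- rep(seq(0, 15) / 16 + 1 / 32, each = 10)
  expect_equal(shannon_entropy(x, n_bins = 16), log(16), tolerance = 1e-12)
  expect_equal(shannon_entropy(rep(2, 50)), 0)
  set.seed(13)
  y <- rnorm(500)
  expect_equal(shannon_entropy(y, 16), shannon_oracle(y, 16),
               tolerance = 1e-12)
  expect_error(shannon_entropy(rnorm(10), n_bins = 1), "bins")
})

test_that("spectral entropy separates tones from broadband noise", {
  expect_lt(spectral_entropy(fixture_signal("sine", 800, f = 10, fs = 200),
                             200), 0.2)
  for (s in 1:20)
    expect_gt(spectral_entropy(fixture_signal("white_noise", 4096, seed = s),
                               200), 0.9)
  w <- fixture_signal("white_noise", 512, seed = 1)
  expect_equal(spectral_entropy(5 * w, 200), spectral_entropy(w, 200),
               tolerance = 1e-9)
  expect_error(spectral_entropy(rep(1, 64), 200), "zero")
})

test_that("nonlinear features ignore constant offsets", {
  set.seed(14)
  x <- fixture_signal("sine", 600, f = 9.3, fs = 200) + 0.3 * rnorm(600)
  off <- 11.5
  expect_equal(approximate_entropy(x + off), approximate_entropy(x),
               tolerance = 1e-8)
  expect_equal(c0_complexity(x + off), c0_complexity(x), tolerance = 1e-8)
  expect_equal(permutation_entropy(x + off), permutation_entropy(x))
  expect_equal(svd_entropy(x + off), svd_entropy(x), tolerance = 1e-8)
  expect_equal(shannon_entropy(x + off), shannon_entropy(x), tolerance = 1e-8)
  expect_equal(spectral_entropy(x + off, 200), spectral_entropy(x, 200),
               tolerance = 1e-8)
  expect_equal(as.numeric(correlation_dimension(x + off, m_range = 3)),
               as.numeric(correlation_dimension(x, m_range = 3)),
               tolerance = 1e-8)
  expect_equal(as.numeric(kolmogorov_entropy(x + off)),
               as.numeric(kolmogorov_entropy(x)), tolerance = 1e-8)
  expect_equal(as.numeric(lyapunov_exponent(x + off)),
               as.numeric(lyapunov_exponent(x)), tolerance = 1e-8)
})

test_that("scale-free nonlinear features ignore positive scaling", {
  set.seed(15)
  x <- fixture_signal("sine", 600, f = 9.3, fs = 200) + 0.3 * rnorm(600)
  sc <- 37
  expect_equal(permutation_entropy(sc * x), permutation_entropy(x))
  expect_equal(spectral_entropy(sc * x, 200), spectral_entropy(x, 200),
               tolerance = 1e-9)
  expect_equal(approximate_entropy(sc * x), approximate_entropy(x),
               tolerance = 1e-9)
  expect_equal(svd_entropy(sc * x), svd_entropy(x), tolerance = 1e-9)
  expect_equal(shannon_entropy(sc * x), shannon_entropy(x), tolerance = 1e-9)
  expect_equal(c0_complexity(sc * x), c0_complexity(x), tolerance = 1e-9)
  expect_equal(as.numeric(lyapunov_exponent(sc * x)),
               as.numeric(lyapunov_exponent(x)), tolerance = 1e-6)
})

test_that("entropy-type features order constant <= sine <= noise", {
  feats <- list(
    function(x) approximate_entropy(x),
    function(x) permutation_entropy(x),
    function(x) svd_entropy(x, m = 10))
  for (s in 1:10) {
    konst <- rep(0.7, 800)
    sine <- fixture_signal("sine", 800, f = 6 + s / 7, fs = 200)
    noise <- fixture_signal("white_noise", 800, seed = 50 + s)
    for (f in feats) {
      expect_lte(f(konst), f(sine) + 1e-12)
      expect_lte(f(sine), f(noise) + 1e-12)
    }
    # spectral entropy is undefined on a constant; compare sine vs noise only
    expect_lte(spectral_entropy(sine, 200), spectral_entropy(noise, 200))
    # amplitude-histogram Shannon entropy orders constant below any signal,
    # but a sine's arcsine amplitude law is *more* uniform over its support
    # than a Gaussian's, so sine <= noise does not hold for it
    expect_lte(shannon_entropy(konst), shannon_entropy(sine))
  }
})
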