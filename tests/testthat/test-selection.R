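test_that("chi-squared scores equal direct contingency evaluation", {
  # counts [[10,20],[30,40]]
  bins <- rep(c(1L, 1L, 2L, 2L), c(10, 20, 30, 40))
  labels <- rep(c("a", "b", "a", "b"), c(10, 20, 30, 40))
  expect_equal(chi2_score(bins, labels), 100 / 126, tolerance = 1e-10)
  expect_equal(chi2_score(bins, labels),
               unname(suppressWarnings(
                 chisq.test(table(bins, labels), correct = FALSE)$statistic)),
               tolerance = 1e-10)
  # identical class-conditional counts -> 0
  b2 <- rep(c(1L, 2L), 20)
  l2 <- rep(c("a", "a", "b", "b"), 10)
  expect_equal(chi2_score(b2, l2), 0, tolerance = 1e-12)
  # perfect separation of two equal classes into two bins, n = 40
  b3 <- rep(c(1L, 2L), each = 20)
  l3 <- rep(c("a", "b"), each = 20)
  expect_equal(chi2_score(b3, l3), 40, tolerance = 1e-12)
})

test_that("mutual information matches the plug-in double sum", {
  set.seed(41)
  x <- rnorm(1000)
  y <- sample(c("a", "b"), 1000, replace = TRUE)
  expect_lt(mutual_information(x, y), 0.02)
  # deterministic median split -> exactly 1 bit
  bins <- as.integer(x > median(x)) + 1L
  yy <- c("neg", "pos")[bins]
  expect_equal(mutual_information(bins, yy), 1, tolerance = 1e-12)
  xb <- quantile_bins(x, 5)
  expect_equal(mutual_information(xb, y), mi_oracle(xb, y), tolerance = 1e-10)
})

test_that("the ANOVA F ratio reproduces the textbook computation", {
  x <- c(0, 1, 10, 11)
  g <- c("a", "a", "b", "b")
  ours <- anova_f(x, g)
  oracle <- anova(lm(x ~ g))$`F value`[1]
  expect_equal(ours, oracle, tolerance = 1e-10)
  expect_equal(anova_f(x + 100, g), ours, tolerance = 1e-10)
  set.seed(42)
  x2 <- rnorm(40)
  g2 <- rep(c("a", "b"), 20)
  expect_equal(anova_f(x2, g2), anova(lm(x2 ~ g2))$`F value`[1],
               tolerance = 1e-10)
  # identical class means -> 0
  expect_equal(anova_f(c(1, 2, 1, 2), c("a", "a", "b", "b")), 0,
               tolerance = 1e-12)
  # zero within-class variance with distinct means -> infinite, ranked first
  expect_identical(anova_f(c(0, 0, 1, 1), c("a", "a", "b", "b")), Inf)
})

test_that("filter scores are permutation-equivariant and null under shuffling", {
  set.seed(43)
  x <- rnorm(200)
  y <- rep(c("negative", "positive"), 100)
  perm <- sample(200)
  expect_equal(chi2_score(x, y), chi2_score(x[perm], y[perm]),
               tolerance = 1e-12)
  expect_equal(mutual_information(x, y),
               mutual_information(x[perm], y[perm]), tolerance = 1e-12)
  expect_equal(anova_f(x, y), anova_f(x[perm], y[perm]), tolerance = 1e-12)
  # label permutation kills association (up to estimator bias)
  xs <- x + 2 * (y == "positive")
  yp <- sample(y)
  expect_lt(chi2_score(xs, yp) / length(y), 0.1)
  expect_lt(mutual_information(xs, yp), 0.05)
})

test_that("permuted-label F scores follow the F distribution", {
  set.seed(44)
  x <- rnorm(60) + 1.5 * rep(c(0, 1), 30)
  y <- rep(c("negative", "positive"), 30)
  fs <- vapply(1:500, function(i) anova_f(x, sample(y)), numeric(1))
  q95 <- quantile(fs, 0.95)
  ref <- qf(0.95, 1, 58)
  expect_lt(abs(q95 - ref) / ref, 0.35)       # Monte-Carlo tolerance
})

test_that("RFE follows the elimination schedule of the algorithm", {
  d <- planted_selection_data(1, n = 60, p = 120)
  r <- rfe(d$x, d$y, q = 20, k = 10)
  expect_equal(r$n_steps, 10)                 # S = (p - q)/k
  expect_length(r$order, 120)
  expect_identical(sort(r$order), 1:120)
  expect_length(r$selected, 20)
  expect_identical(sort(r$order[1:20]), r$selected)
  # k = p - q: single step equals one-shot |w| ranking
  r1 <- rfe(d$x, d$y, q = 20, k = 100)
  expect_equal(r1$n_steps, 1)
  w <- abs(emorhythm:::svm_weights(d$x, d$y))
  expect_identical(sort(r1$selected), sort(order(-w)[1:20]))
  expect_error(rfe(d$x, d$y, q = 120), "smaller")
})

test_that("RFE with k = 1 and block elimination agree on well-separated weights", {
  # four informative columns with staggered strong effects, so every
  # survivor's |w| is separated from the noise features by a wide gap
  set.seed(2)
  n <- 120; p <- 24
  y <- rep(c("negative", "positive"), each = n / 2)
  x <- matrix(rnorm(n * p, sd = 0.3), n, p)
  info <- c(4, 9, 14, 19)
  for (i in seq_along(info))
    x[y == "positive", info[i]] <- x[y == "positive", info[i]] + 2 + i
  ra <- rfe(x, y, q = 4, k = 1)
  rb <- rfe(x, y, q = 4, k = 4)
  expect_identical(ra$selected, rb$selected)
  expect_identical(ra$selected, as.integer(info))
})

test_that("RFE recovers planted informative features", {
  hits <- 0
  for (s in 1:20) {
    d <- planted_selection_data(s)
    r <- rfe(d$x, d$y, q = 10, k = 10)
    if (all(d$informative %in% r$selected)) hits <- hits + 1
  }
  expect_gte(hits, 18)
})

test_that("the L1 path is empty at strong penalty and grows with C", {
  d <- planted_selection_data(3, n = 80, p = 40)
  xs <- scale(d$x)
  expect_length(l1_select(xs, d$y, C = 1e-6)$selected, 0)
  sizes <- vapply(seq(0.01, 1, by = 0.01), function(C)
    length(l1_select(xs, d$y, C = C)$selected), numeric(1))
  viol <- sum(diff(sizes) < 0)
  expect_lte(viol, 5)                          # <= 5% of 99 steps
  expect_gt(sizes[100], sizes[1])
})

test_that("L1 selection recovers planted informative features", {
  hits <- 0
  for (s in 1:20) {
    d <- planted_selection_data(s + 100)
    r <- l1_select(scale(d$x), d$y, C = 0.05)
    if (all(d$informative %in% r$selected)) hits <- hits + 1
  }
  expect_gte(hits, 18)
})

test_that("select_features dispatches and returns consistent rankings", {
  d <- planted_selection_data(4, n = 60, p = 30)
  for (m in c("chi2", "mi", "f")) {
    r <- select_features(d$x, d$y, m, n_select = 5)
    expect_s3_class(r, "ranked_selection")
    expect_identical(sort(r$order), 1:30)
    expect_length(r$selected, 5)
    expect_identical(r$selected, sort(r$order[1:5]))
    expect_true(all(is.finite(r$scores)))
  }
})
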