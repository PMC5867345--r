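# Independent brute-force oracles. These deliberately share no code with the
# package implementations they check.

# Pincus ApEn via a literal double loop over templates
apen_oracle <- function(x, m, r_abs) {
  phi <- function(mm) {
    N <- length(x) - mm + 1
    tmpl <- sapply(seq_len(N), function(i) x[i:(i + mm - 1)])
    cs <- vapply(seq_len(N), function(i) {
      cnt <- 0
      for (j in seq_len(N))
        if (max(abs(tmpl[, i] - tmpl[, j])) <= r_abs) cnt <- cnt + 1
      log(cnt / N)
    }, numeric(1))
    mean(cs)
  }
  phi(m) - phi(m + 1)
}

# permutation entropy via explicit ordinal-pattern string counting
pe_oracle <- function(x, m, tau = 1) {
  n <- length(x) - (m - 1) * tau
  pats <- vapply(seq_len(n), function(i) {
    paste(order(x[seq(i, by = tau, length.out = m)]), collapse = "")
  }, character(1))
  p <- table(pats) / n
  -sum(p * log(p)) / log(factorial(m))
}

# Shannon entropy re-computed from explicit bin counts
shannon_oracle <- function(x, n_bins) {
  rng <- range(x)
  if (diff(rng) == 0) return(0)
  cuts <- seq(rng[1], rng[2], length.out = n_bins + 1)
  cnt <- vapply(seq_len(n_bins), function(b) {
    lo <- cuts[b]; hi <- cuts[b + 1]
    sum(if (b < n_bins) x >= lo & x < hi else x >= lo & x <= hi)
  }, numeric(1))
  p <- cnt / length(x)
  p <- p[p > 0]
  -sum(p * log(p))
}

# SVD entropy from a hand-built trajectory matrix
svdent_oracle <- function(x, m, tau = 1) {
  x <- x - mean(x)
  n <- length(x) - (m - 1) * tau
  M <- t(sapply(seq_len(n), function(i) x[seq(i, by = tau, length.out = m)]))
  s <- svd(M)$d
  p <- s / sum(s)
  p <- p[p > 0]
  -sum(p * log(p)) / log(m)
}

# plug-in mutual information (bits) as a literal double sum
mi_oracle <- function(bins, labels) {
  tab <- table(bins, labels)
  P <- tab / sum(tab)
  total <- 0
  for (i in seq_len(nrow(P))) for (j in seq_len(ncol(P))) {
    if (P[i, j] > 0)
      total <- total + P[i, j] * log2(P[i, j] / (sum(P[i, ]) * sum(P[, j])))
  }
  total
}

# correlation integral C(eps) by a direct distance scan at one embedding
# dimension (Chebyshev norm, Theiler exclusion)
corrint_oracle <- function(x, m, tau, eps, theiler) {
  n <- length(x) - (m - 1) * tau
  E <- sapply(seq_len(m), function(k) x[(1 + (k - 1) * tau):((k - 1) * tau + n)])
  cnt <- 0; tot <- 0
  for (i in seq_len(n - theiler - 1)) {
    js <- (i + theiler + 1):n
    d <- apply(abs(E[js, , drop = FALSE] -
                     matrix(E[i, ], length(js), m, byrow = TRUE)), 1, max)
    cnt <- cnt + colSums(outer(d, eps, "<"))
    tot <- tot + length(js)
  }
  cnt / tot
}

# per-node clustering coefficients by exhaustive triple scan
clustering_oracle <- function(adj) {
  n <- nrow(adj)
  vapply(seq_len(n), function(i) {
    nb <- which(adj[i, ] != 0)
    k <- length(nb)
    if (k < 2) return(0)
    tri <- 0
    for (a in seq_len(k - 1)) for (b in (a + 1):k)
      if (adj[nb[a], nb[b]] != 0) tri <- tri + 1
    2 * tri / (k * (k - 1))
  }, numeric(1))
}

# planted two-informative-feature dataset for selection-recovery checks:
# 100 noise columns, 2 informative columns shifted by `effect` sd between
# balanced classes
planted_selection_data <- function(seed, n = 100, p = 100, effect = 2) {
  set.seed(seed)
  y <- rep(c("negative", "positive"), each = n / 2)
  x <- matrix(rnorm(n * p), n, p)
  info <- c(round(p / 4), round(3 * p / 4))
  x[y == "positive", info] <- x[y == "positive", info] + effect
  list(x = x, y = y, informative = info)
}

# small, fast generator configs used across the suite
tiny_config <- function(seed, n_subjects = 3, n_trials_per_class = 2,
                        n_channels = 4, ...) {
  generator_config(n_subjects = n_subjects,
                   n_trials_per_class = n_trials_per_class,
                   n_channels = n_channels, fs = 128, duration = 8,
                   seed = seed, ...)
}
loso_config <- function(seed, ...) {
  generator_config(n_subjects = 6, n_trials_per_class = 4, n_channels = 4,
                   fs = 128, duration = 12, seed = seed, ...)
}
null_config <- function(seed, ...) {
  generator_config(n_subjects = 5, n_trials_per_class = 3, n_channels = 4,
                   fs = 128, duration = 12, class_beta_shift = 1,
                   class_corr_gap = 0, seed = seed, ...)
}
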