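fake_windows <- function(obs) {
  # obs: windows x channels matrix -> long window-level table
  data.frame(subject_id = "S01", trial_id = "t1", label = "negative",
             rhythm = "beta", channel = rep(colnames(obs), each = nrow(obs)),
             feature_id = 3, window_index = rep(seq_len(nrow(obs)),
                                                ncol(obs)),
             value = as.numeric(obs), stringsAsFactors = FALSE)
}

test_that("channel correlation matches the textbook formula", {
  set.seed(81)
  obs <- matrix(rnorm(60), 20, 3, dimnames = list(NULL, c("C3", "C4", "CZ")))
  obs[, 2] <- obs[, 1]                         # identical sequences
  m <- channel_correlation(fake_windows(obs))
  expect_equal(m["C3", "C4"], 1, tolerance = 1e-12)
  # direct covariance / sd oracle
  o13 <- mean((obs[, 1] - mean(obs[, 1])) * (obs[, 3] - mean(obs[, 3]))) /
    (sd(obs[, 1]) * sd(obs[, 3])) * nrow(obs) / (nrow(obs) - 1)
  expect_equal(m["C3", "CZ"], o13, tolerance = 1e-12)
  expect_true(isSymmetric(m))
  expect_true(all(diag(m) == 1))
})

test_that("independent channels stay nearly uncorrelated", {
  for (s in 1:10) {
    set.seed(200 + s)
    obs <- matrix(rnorm(2500), 500, 5,
                  dimnames = list(NULL, paste0("C", 1:5)))
    m <- channel_correlation(fake_windows(obs))
    expect_lt(max(abs(m[upper.tri(m)])), 0.15)
  }
})

test_that("zero-variance channels are flagged undefined", {
  obs <- matrix(rnorm(40), 20, 2, dimnames = list(NULL, c("C3", "C4")))
  obs[, 2] <- 1
  expect_warning(m <- channel_correlation(fake_windows(obs)), NA)
  expect_true(all(is.na(m["C4", ])))
  expect_equal(m["C3", "C3"], 1)
})

test_that("mean global correlation averages the strict upper triangle", {
  expect_equal(mean_global_correlation(diag(5)), 0)
  expect_equal(mean_global_correlation(matrix(1, 4, 4)), 1)
  m <- diag(3); m[1, 2] <- m[2, 1] <- 0.6; m[1, 3] <- m[3, 1] <- 0.2
  m[2, 3] <- m[3, 2] <- 0.4
  expect_equal(mean_global_correlation(m), 0.4)
})

test_that("binarization uses strict signed thresholds and a zero diagonal", {
  m <- rbind(c(1, 0.7, -0.5), c(0.7, 1, 0.3), c(-0.5, 0.3, 1))
  b <- binarize(m, 0.5)
  expect_equal(unclass(b)[1, 2], 1)
  expect_equal(unclass(b)[1, 3], 0)            # negative entries never connect
  expect_true(all(diag(unclass(b)) == 0))
  for (th in c(0.05, 0.4, 0.9))
    expect_equal(unclass(binarize(m, th))[1, 3], 0)
  low <- binarize(m, 0.1)
  expect_equal(sum(unclass(low)), 4)           # 0.7 and 0.3 edges, both ways
  expect_error(binarize(m, 1.2), "threshold")
  # edge count is non-increasing in the threshold
  set.seed(82)
  r <- cor(matrix(rnorm(900), 30, 30))
  counts <- vapply(seq(0.05, 0.95, 0.05),
                   function(th) sum(unclass(binarize(r, th))), numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("clustering coefficients equal exhaustive triangle counting", {
  k4 <- matrix(1, 4, 4); diag(k4) <- 0
  cc <- clustering_coefficients(k4)
  expect_equal(unname(cc$per_node), rep(1, 4))
  expect_equal(cc$global, 1)
  star <- matrix(0, 5, 5); star[1, 2:5] <- star[2:5, 1] <- 1
  cs <- clustering_coefficients(star)
  expect_equal(unname(cs$per_node), rep(0, 5))
  for (g in 1:20) {
    set.seed(g)
    adj <- matrix(0, 62, 62)
    adj[upper.tri(adj)] <- rbinom(62 * 61 / 2, 1, 0.2)
    adj <- adj + t(adj)
    cc <- clustering_coefficients(adj)
    expect_equal(unname(cc$per_node), clustering_oracle(adj),
                 tolerance = 1e-12)
    expect_equal(cc$global, mean(clustering_oracle(adj)), tolerance = 1e-12)
  }
})

test_that("the threshold scan finds planted group differences, not null ones", {
  # identical group matrices -> nowhere significant
  set.seed(83)
  mats <- lapply(1:6, function(i) {
    m <- cor(matrix(rnorm(400), 50, 8))
    dimnames(m) <- list(paste0("C", 1:8), paste0("C", 1:8))
    m
  })
  conn0 <- structure(list(
    matrices = stats::setNames(lapply(mats, function(m)
      list(negative = m, positive = m)), paste0("S", 1:6)),
    feature_id = 3, rhythm = "beta"), class = "group_connectivity")
  sc0 <- threshold_scan(conn0)
  expect_equal(nrow(sc0$significant_ranges), 0)

  # planted gap: negative matrices uniformly more correlated
  make_m <- function(rho, n = 8) {
    m <- matrix(rho, n, n); diag(m) <- 1
    m <- m + 0.03 * cor(matrix(rnorm(40 * n), 40, n))
    m <- (m + t(m)) / 2; diag(m) <- 1
    dimnames(m) <- list(paste0("C", 1:n), paste0("C", 1:n))
    m
  }
  conn1 <- structure(list(
    matrices = stats::setNames(lapply(1:8, function(i)
      list(negative = make_m(0.55), positive = make_m(0.35))),
      paste0("S", 1:8)),
    feature_id = 3, rhythm = "beta"), class = "group_connectivity")
  sc1 <- threshold_scan(conn1)
  expect_gt(nrow(sc1$significant_ranges), 0)
  # reported ranges are maximal contiguous runs of the grid
  for (i in seq_len(nrow(sc1$significant_ranges))) {
    lo <- sc1$significant_ranges$from[i]; hi <- sc1$significant_ranges$to[i]
    inside <- sc1$scan$threshold >= lo - 1e-9 & sc1$scan$threshold <= hi + 1e-9
    expect_true(all(sc1$scan$p[inside] < 0.05))
    prev <- which(abs(sc1$scan$threshold - (lo - 0.01)) < 1e-9)
    if (length(prev))
      expect_false(isTRUE(sc1$scan$p[prev] < 0.05))
  }
})

test_that("feature intercorrelation ties variance to Hjorth activity", {
  tab <- assemble(generate_dataset(tiny_config(84)),
                  feature_ids = c(2, 3, 4, 5))
  m <- feature_intercorrelation(tab, "beta")
  expect_equal(m["f3", "f4"], 1, tolerance = 1e-12)  # activity == variance
  expect_true(isSymmetric(unname(m)))
  expect_true(all(diag(m) == 1))
  expect_true(all(m >= -1 - 1e-12 & m <= 1 + 1e-12, na.rm = TRUE))
})

test_that("paired group tests star-code the canonical thresholds", {
  expect_identical(emorhythm:::p_stars(c(0.2, 0.049, 0.009, 0.0009, 0.05,
                                         0.01, 0.001)),
                   c("", "*", "**", "***", "", "*", "**"))
  df <- data.frame(subject_id = rep(paste0("S", 1:10), 2),
                   group = rep(c("negative", "positive"), each = 10),
                   value = c(rep(1, 10), rep(1, 10)))
  r <- group_ttests(df)
  expect_equal(r$p, 1)
  expect_identical(r$stars, "")
  set.seed(85)
  df2 <- data.frame(subject_id = rep(paste0("S", 1:10), 2),
                    group = rep(c("negative", "positive"), each = 10),
                    value = c(5 + rnorm(10, 0, 0.01), rnorm(10, 0, 0.01)))
  r2 <- group_ttests(df2)
  expect_lt(r2$p, 0.001)
  expect_identical(r2$stars, "***")
  oracle <- t.test(df2$value[1:10], df2$value[11:20], paired = TRUE)$p.value
  expect_equal(r2$p, oracle, tolerance = 1e-12)
})

test_that("group connectivity extracts per-subject matrices from the pipeline", {
  tab <- assemble(generate_dataset(tiny_config(86, n_trials_per_class = 3)),
                  feature_ids = 3, keep_windows = TRUE)
  conn <- group_connectivity(tab, 3, "beta")
  expect_s3_class(conn, "group_connectivity")
  expect_length(conn$matrices, 3)
  m <- conn$matrices[[1]]$negative
  expect_true(isSymmetric(unname(m)))
  expect_equal(unname(diag(m)), rep(1, 4))
  gm <- conn$group_means$negative
  expect_true(isSymmetric(unname(gm)))
  expect_equal(unname(diag(gm)), rep(1, 4))
  expect_error(group_connectivity(
    assemble(generate_dataset(tiny_config(87)), feature_ids = 3), 3, "beta"),
    "keep_windows")
})
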