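#' Quantile discretization of a continuous feature
#'
#' Five quantile bins computed on the supplied values (training data when
#' used inside the LOSO harness). Duplicate quantile boundaries collapse, so
#' heavily tied features may yield fewer bins.
#'
#' @param x numeric vector.
#' @param n_bins number of quantile bins, default 5.
#' @return integer bin indices.
#' @export
quantile_bins <- function(x, n_bins = 5) {
  br <- unique(quantile(x, probs = seq(0, 1, length.out = n_bins + 1)))
  if (length(br) < 2) return(rep(1L, length(x)))
  as.integer(cut(x, br, include.lowest = TRUE))
}

# observed and expected counts of a feature-bin x class contingency table;
# empty bin rows simply drop out (equivalent to merging them away)
contingency <- function(bins, labels) {
  O <- table(bins, labels)
  O <- O[rowSums(O) > 0, colSums(O) > 0, drop = FALSE]
  E <- outer(rowSums(O), colSums(O)) / sum(O)
  list(O = O, E = E)
}

#' Chi-squared relevance score of one feature
#'
#' Pearson chi-squared statistic `sum (O - E)^2 / E` of the contingency
#' table between the discretized feature and the class labels; larger means
#' stronger association. Continuous features are discretized into quantile
#' bins first.
#'
#' @param x feature column (numeric, discretized internally) or an integer
#'   vector of pre-assigned bins.
#' @param labels class labels.
#' @param n_bins quantile bins for continuous input, default 5.
#' @export
chi2_score <- function(x, labels, n_bins = 5) {
  bins <- if (is.integer(x) || is.factor(x)) x else quantile_bins(x, n_bins)
  ct <- contingency(bins, labels)
  sum((ct$O - ct$E)^2 / ct$E)
}

#' Mutual information between one feature and the class labels
#'
#' Histogram plug-in estimator `I(X;Y) = H(X) + H(Y) - H(X,Y)` on quantile
#' bins, reported in bits.
#'
#' @inheritParams chi2_score
#' @export
mutual_information <- function(x, labels, n_bins = 5) {
  bins <- if (is.integer(x) || is.factor(x)) x else quantile_bins(x, n_bins)
  ct <- contingency(bins, labels)
  P <- ct$O / sum(ct$O)
  px <- rowSums(P); py <- colSums(P)
  H <- function(p) { p <- p[p > 0]; -sum(p * log2(p)) }
  max(0, H(px) + H(py) - H(as.numeric(P)))
}

#' One-way ANOVA F ratio of one feature
#'
#' `F = sigma2_between / sigma2_within` with
#' `sigma2_between = sum_j N_j (xbar_j - xbar)^2 / (J - 1)` and
#' `sigma2_within = (SS_total - sum_j N_j (xbar_j - xbar)^2) / (N - J)`.
#' A feature with zero within-class variance but distinct class means gets
#' an infinite score (ranked first).
#'
#' @param x numeric feature column.
#' @param labels class labels (>= 2 classes, each with >= 2 samples).
#' @export
anova_f <- function(x, labels) {
  g <- split(x, labels)
  g <- g[vapply(g, length, integer(1)) > 0]
  J <- length(g); N <- length(x)
  if (J < 2) stop("need at least 2 classes")
  if (any(vapply(g, length, integer(1)) < 2))
    stop("every class needs at least 2 samples")
  xbar <- mean(x)
  ssb <- sum(vapply(g, function(v) length(v) * (mean(v) - xbar)^2, numeric(1)))
  sst <- sum((x - xbar)^2)
  s2b <- ssb / (J - 1)
  s2w <- (sst - ssb) / (N - J)
  if (s2w == 0) return(Inf)
  s2b / s2w
}

# linear SVM weight vector |w| via e1071 (w = t(alpha y) SV)
svm_weights <- function(x, y, cost = 1) {
  fit <- e1071::svm(x, factor(y), kernel = "linear", cost = cost,
                    scale = FALSE)
  as.numeric(crossprod(fit$coefs, fit$SV))
}

#' Recursive feature elimination with a linear SVM
#'
#' Backward elimination: `S = (p - q) / k` steps; each step retrains the
#' linear SVM on the surviving features, removes the `k` features with the
#' smallest absolute weights (ties broken by column index) and writes them
#' into the tail of the final ranking. The last step is truncated when
#' `p - q` is not a multiple of `k`.
#'
#' @param x feature matrix (n x p).
#' @param y class labels.
#' @param q desired number of surviving features (< p).
#' @param k features eliminated per step, default 10.
#' @param cost SVM cost parameter, default 1.
#' @return A `ranked_selection`: `order` (best first; survivors ranked by
#'   final |w|, then eliminated features in reverse elimination order),
#'   `scores` (|w| at elimination or in the final model), `selected`,
#'   `n_steps`.
#' @export
rfe <- function(x, y, q, k = 10, cost = 1) {
  p <- ncol(x)
  if (q >= p) stop("q must be smaller than the feature count")
  surviving <- seq_len(p)
  tail_rank <- integer(0)
  scores <- numeric(p)
  step <- 0L
  while (length(surviving) > q) {
    step <- step + 1L
    w <- tryCatch(svm_weights(x[, surviving, drop = FALSE], y, cost),
                  error = function(e)
                    stop("SVM training failed at RFE step ", step, ": ",
                         conditionMessage(e)))
    aw <- abs(w)
    drop_n <- min(k, length(surviving) - q)
    ord <- order(aw, seq_along(aw))          # ties -> lower column index first
    out <- surviving[ord[seq_len(drop_n)]]
    scores[out] <- aw[ord[seq_len(drop_n)]]
    tail_rank <- c(out, tail_rank)           # later eliminations rank higher
    surviving <- setdiff(surviving, out)
  }
  w_final <- abs(svm_weights(x[, surviving, drop = FALSE], y, cost))
  scores[surviving] <- w_final
  head_rank <- surviving[order(-w_final, surviving)]
  structure(list(order = c(head_rank, tail_rank), scores = scores,
                 selected = sort(surviving), method = "rfe",
                 n_steps = step, params = list(q = q, k = k, cost = cost)),
            class = "ranked_selection")
}

#' L1-penalized linear SVM feature selection
#'
#' Minimizes `||w||_1 + C * sum_i max(0, 1 - y_i (w'x_i + b))^2` (squared
#' hinge; the intercept is unpenalized) by proximal gradient descent with
#' Nesterov acceleration (FISTA). Features with nonzero weights form the
#' selected set; C trades loss against sparsity, so the selection is empty
#' in the strong-penalty limit C -> 0 and grows with C.
#'
#' @param x feature matrix.
#' @param y class labels (two classes).
#' @param C loss weight (> 0).
#' @param max_iter,tol solver controls.
#' @return A `ranked_selection` with `scores = |w|` and `selected` the
#'   nonzero-weight features.
#' @export
l1_select <- function(x, y, C, max_iter = 3000, tol = 1e-7) {
  if (C <= 0) stop("C must be positive")
  yy <- ifelse(y == sort(unique(y))[1], -1, 1)
  n <- nrow(x); p <- ncol(x)
  # Lipschitz constant of the smooth part: 2C * lambda_max([X 1]'[X 1])
  Xa <- cbind(x, 1)
  L <- 2 * C * (svd(Xa, nu = 0, nv = 0)$d[1])^2
  w <- rep(0, p); b <- 0
  zw <- w; zb <- b; tk <- 1
  obj_old <- Inf
  for (it in seq_len(max_iter)) {
    marg <- 1 - yy * (x %*% zw + zb)
    act <- marg > 0
    gw <- -2 * C * crossprod(x[act, , drop = FALSE], (yy * marg)[act])
    gb <- -2 * C * sum((yy * marg)[act])
    w_new <- zw - gw / L
    w_new <- sign(w_new) * pmax(abs(w_new) - 1 / L, 0)   # soft threshold
    b_new <- zb - gb / L
    t_new <- (1 + sqrt(1 + 4 * tk^2)) / 2
    zw <- w_new + (tk - 1) / t_new * (w_new - w)
    zb <- b_new + (tk - 1) / t_new * (b_new - b)
    w <- w_new; b <- b_new; tk <- t_new
    if (it %% 25 == 0) {
      m2 <- pmax(0, 1 - yy * (x %*% w + b))
      obj <- sum(abs(w)) + C * sum(m2^2)
      if (is.finite(obj_old) && abs(obj_old - obj) <= tol * max(1, obj)) break
      obj_old <- obj
    }
  }
  if (it == max_iter)
    warning("L1 solver hit max_iter without meeting the tolerance")
  aw <- abs(as.numeric(w))
  structure(list(order = order(-aw, seq_len(p)), scores = aw,
                 selected = which(aw > 0), method = "l1",
                 weights = as.numeric(w), intercept = b,
                 params = list(C = C)),
            class = "ranked_selection")
}

#' Rank features of a table by a selection criterion
#'
#' Dispatches to the five selection strategies. Filter criteria (chi2, mi,
#' f) score each column independently; rfe and l1 are multivariate.
#'
#' @param x numeric feature matrix (training rows only).
#' @param y class labels aligned with the rows of `x`.
#' @param method one of `"chi2"`, `"mi"`, `"f"`, `"rfe"`, `"l1"`.
#' @param n_select features to keep (`q` for rfe; ignored by l1, whose
#'   sparsity comes from `C`).
#' @param ... forwarded to the criterion (`n_bins`, `k`, `C`, ...).
#' @return A `ranked_selection`.
#' @export
select_features <- function(x, y, method = c("chi2", "mi", "f", "rfe", "l1"),
                            n_select = ncol(x), ...) {
  method <- match.arg(method)
  if (method %in% c("chi2", "mi", "f")) {
    fun <- switch(method, chi2 = chi2_score, mi = mutual_information,
                  f = anova_f)
    scores <- apply(x, 2, fun, labels = y, ...)
    ord <- order(-scores, seq_len(ncol(x)))
    structure(list(order = ord, scores = scores,
                   selected = sort(ord[seq_len(min(n_select, ncol(x)))]),
                   method = method, params = list(n_select = n_select)),
              class = "ranked_selection")
  } else if (method == "rfe") {
    rfe(x, y, q = n_select, ...)
  } else {
    l1_select(x, y, ...)
  }
}

#' @export
print.ranked_selection <- function(x, ...) {
  cat(sprintf("<ranked_selection %s> %d features ranked, %d selected\n",
              x$method, length(x$order), length(x$selected)))
  invisible(x)
}
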