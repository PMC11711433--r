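# Shared fixtures and independent oracles used across the suite.

`%||%` <- function(a, b) if (is.null(a)) b else a

# Central finite-difference gradient of a scalar-valued function of one array.
numerical_grad <- function(f, x, eps = 1e-5) {
  g <- array(0, dim(x) %||% length(x))
  for (i in seq_along(x)) {
    xp <- x; xp[i] <- xp[i] + eps
    xm <- x; xm[i] <- xm[i] - eps
    g[i] <- (f(xp) - f(xm)) / (2 * eps)
  }
  g
}

# Brute-force scaled dot-product attention, scalar-level loops only.
brute_attention <- function(Q, K, V, dk) {
  nq <- nrow(Q); nk <- nrow(K)
  out <- matrix(0, nq, ncol(V))
  for (i in seq_len(nq)) {
    scores <- numeric(nk)
    for (j in seq_len(nk)) {
      s <- 0
      for (l in seq_len(ncol(Q))) s <- s + Q[i, l] * K[j, l]
      scores[j] <- s / sqrt(dk)
    }
    w <- exp(scores - max(scores))
    w <- w / sum(w)
    for (j in seq_len(nk)) out[i, ] <- out[i, ] + w[j] * V[j, ]
  }
  out
}

# Brute-force binary metrics straight from the printed formulas.
brute_binary_metrics <- function(tp, tn, fp, fn) {
  div <- function(num, den) if (den == 0) 0 else num / den
  acc <- div(tp + tn, tp + tn + fp + fn)
  sens <- div(tp, tp + fn)
  prec <- div(tp, tp + fp)
  spec <- div(tn, tn + fp)
  f1 <- div(2 * prec * sens, prec + sens)
  mcc_den <- sqrt(tp + fp) * sqrt(tp + fn) * sqrt(tn + fp) * sqrt(tn + fn)
  mcc <- if (mcc_den == 0) 0 else (tp * tn - fp * fn) / mcc_den
  n <- tp + tn + fp + fn
  po <- div(tp + tn, n)
  pe <- if (n == 0) 0 else ((tp + fn) * (tp + fp) + (tn + fp) * (tn + fn)) / n^2
  kap <- if (pe == 1) 0 else (po - pe) / (1 - pe)
  list(accuracy = acc, sensitivity = sens, precision = prec, specificity = spec,
       f1 = f1, mcc = mcc, po = po, pe = pe, kappa = kap)
}

# Mann-Whitney pair-counting AUC with ties counted as 1/2.
brute_auc <- function(y, scores) {
  pos <- scores[y == 1]; neg <- scores[y == 0]
  tot <- 0
  for (p in pos) for (q in neg) tot <- tot + (p > q) + 0.5 * (p == q)
  tot / (length(pos) * length(neg))
}

tiny_image <- function(h, w, seed = 1) {
  set.seed(seed)
  array(runif(h * w * 3), c(h, w, 3))
}
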