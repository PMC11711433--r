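# Reverse-mode automatic differentiation on dense arrays.
#
# Define-by-run tape: every operation returns an `ad_node` holding its value,
# its parent nodes and a backward closure mapping the incoming gradient to the
# parents' gradients. `ad_backward()` topologically sorts the graph from the
# loss node and accumulates gradients into every node with `requires = TRUE`.
# Values are plain R arrays (column-major); matrix products hit BLAS.

.ad_counter <- new.env(parent = emptyenv())
.ad_counter$id <- 0L

ad_next_id <- function() {
  .ad_counter$id <- .ad_counter$id + 1L
  .ad_counter$id
}

#' Create an autodiff graph node
#'
#' @param value numeric array (or matrix/vector) holding the forward value.
#' @param parents list of `ad_node` parents this node was computed from.
#' @param backward function(grad) returning a list of gradients, one per
#'   parent, each conformable with the parent's value (or NULL to skip).
#' @param requires does any ancestor require a gradient?
#' @return an object of class `ad_node`.
#' @keywords internal
ad_node <- function(value, parents = list(), backward = NULL,
                    requires = any(vapply(parents, function(p) p$requires, logical(1)))) {
  node <- new.env(parent = emptyenv())
  node$id <- ad_next_id()
  node$value <- value
  node$parents <- parents
  node$backward <- backward
  node$requires <- isTRUE(requires)
  node$grad <- NULL
  class(node) <- "ad_node"
  node
}

#' Wrap a constant (no gradient tracked)
#' @keywords internal
ad_const <- function(value) ad_node(value, requires = FALSE)

#' Wrap a trainable parameter (gradient tracked)
#' @keywords internal
ad_param <- function(value) ad_node(value, requires = TRUE)

as_ad <- function(x) if (inherits(x, "ad_node")) x else ad_const(x)

ad_value <- function(x) if (inherits(x, "ad_node")) x$value else x

# Topological order (parents before children) from a root node.
ad_topo_sort <- function(root) {
  order <- vector("list", 256L)
  n_out <- 0L
  seen <- new.env(parent = emptyenv())
  stack <- list(list(node = root, stage = 1L))
  while (length(stack) > 0L) {
    top <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    node <- top$node
    key <- as.character(node$id)
    if (top$stage == 1L) {
      if (!is.null(seen[[key]])) next
      seen[[key]] <- TRUE
      stack[[length(stack) + 1L]] <- list(node = node, stage = 2L)
      for (p in node$parents) {
        if (p$requires && is.null(seen[[as.character(p$id)]])) {
          stack[[length(stack) + 1L]] <- list(node = p, stage = 1L)
        }
      }
    } else {
      n_out <- n_out + 1L
      if (n_out > length(order)) order <- c(order, vector("list", length(order)))
      order[[n_out]] <- node
    }
  }
  order[seq_len(n_out)]
}

#' Run backpropagation from a (scalar) loss node
#'
#' Accumulates `$grad` on every ancestor node with `requires = TRUE`.
#' @param root the output `ad_node`; its seed gradient defaults to 1.
#' @param seed optional gradient conformable with `root$value`.
#' @keywords internal
ad_backward <- function(root, seed = NULL) {
  if (!root$requires) return(invisible(NULL))
  order <- ad_topo_sort(root)
  for (node in order) node$grad <- NULL
  root$grad <- if (is.null(seed)) array(1, dim = dim(root$value) %||% length(root$value)) else seed
  for (i in rev(seq_along(order))) {
    node <- order[[i]]
    if (is.null(node$backward) || is.null(node$grad)) next
    grads <- node$backward(node$grad)
    for (j in seq_along(node$parents)) {
      p <- node$parents[[j]]
      if (!p$requires || is.null(grads[[j]])) next
      p$grad <- if (is.null(p$grad)) grads[[j]] else p$grad + grads[[j]]
    }
  }
  invisible(NULL)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# --- elementwise and linear-algebra primitives ------------------------------

ad_add <- function(a, b) {
  a <- as_ad(a); b <- as_ad(b)
  ad_node(a$value + b$value, list(a, b), function(g) list(g, g))
}

ad_sub <- function(a, b) {
  a <- as_ad(a); b <- as_ad(b)
  ad_node(a$value - b$value, list(a, b), function(g) list(g, -g))
}

ad_mul <- function(a, b) {
  a <- as_ad(a); b <- as_ad(b)
  ad_node(a$value * b$value, list(a, b),
          function(g) list(g * b$value, g * a$value))
}

ad_scale <- function(a, s) {
  a <- as_ad(a)
  ad_node(a$value * s, list(a), function(g) list(g * s))
}

ad_matmul <- function(a, b) {
  a <- as_ad(a); b <- as_ad(b)
  ad_node(a$value %*% b$value, list(a, b),
          function(g) list(g %*% t(b$value), t(a$value) %*% g))
}

# x: (n, d) matrix; bias: length-d vector added to every row.
ad_add_rowvec <- function(x, bias) {
  x <- as_ad(x); bias <- as_ad(bias)
  ad_node(sweep(x$value, 2L, as.vector(bias$value), "+"), list(x, bias),
          function(g) list(g, colSums(g)))
}

# x: array whose last dim is C; bias: length-C vector.
ad_add_channel <- function(x, bias) {
  x <- as_ad(x); bias <- as_ad(bias)
  d <- dim(x$value)
  cdim <- d[length(d)]
  per <- prod(d[-length(d)])
  ad_node(x$value + rep(as.vector(bias$value), each = per), list(x, bias),
          function(g) list(g, colSums(matrix(g, nrow = per, ncol = cdim))))
}

# Multiply array x (dims ..., C) by map m (same leading dims, trailing dim 1
# or absent), broadcasting over channels.
ad_mul_bcast_channel <- function(x, m) {
  x <- as_ad(x); m <- as_ad(m)
  d <- dim(x$value)
  cdim <- d[length(d)]
  per <- prod(d[-length(d)])
  mv <- as.vector(m$value)
  stopifnot(length(mv) == per)
  ad_node(x$value * as.vector(mv), list(x, m), function(g) {
    gm <- rowSums(matrix(g * x$value, nrow = per, ncol = cdim))
    dim(gm) <- dim(m$value) %||% length(mv)
    list(g * as.vector(mv), gm)
  })
}

ad_reshape <- function(x, dims) {
  x <- as_ad(x)
  v <- x$value
  old <- dim(v) %||% length(v)
  dim(v) <- dims
  ad_node(v, list(x), function(g) { dim(g) <- old; list(g) })
}

ad_aperm <- function(x, perm) {
  x <- as_ad(x)
  inv <- order(perm)
  ad_node(aperm(x$value, perm), list(x), function(g) list(aperm(g, inv)))
}

# Select channels (last dim) of a 4-d array.
ad_slice_channels <- function(x, idx) {
  x <- as_ad(x)
  d <- dim(x$value)
  stopifnot(length(d) == 4L)
  ad_node(x$value[, , , idx, drop = FALSE], list(x), function(g) {
    gx <- array(0, d)
    gx[, , , idx] <- g
    list(gx)
  })
}

ad_concat_channels <- function(a, b) {
  a <- as_ad(a); b <- as_ad(b)
  da <- dim(a$value); db <- dim(b$value)
  stopifnot(length(da) == 4L, all(da[1:3] == db[1:3]))
  out <- array(0, c(da[1:3], da[4] + db[4]))
  out[, , , seq_len(da[4])] <- a$value
  out[, , , da[4] + seq_len(db[4])] <- b$value
  ad_node(out, list(a, b), function(g) {
    list(g[, , , seq_len(da[4]), drop = FALSE],
         g[, , , da[4] + seq_len(db[4]), drop = FALSE])
  })
}

# --- activations ------------------------------------------------------------

#' Gaussian error linear unit (exact, Phi-based)
#' @param x numeric array or `ad_node`.
#' @return same type as the input.
#' @keywords internal
ad_gelu <- function(x) {
  x <- as_ad(x)
  v <- x$value
  ad_node(v * stats::pnorm(v), list(x),
          function(g) list(g * (stats::pnorm(v) + v * stats::dnorm(v))))
}

ad_sigmoid <- function(x) {
  x <- as_ad(x)
  s <- 1 / (1 + exp(-x$value))
  ad_node(s, list(x), function(g) list(g * s * (1 - s)))
}

# Row-wise softmax of a matrix.
ad_softmax_rows <- function(x) {
  x <- as_ad(x)
  v <- x$value
  m <- v - apply(v, 1L, max)
  e <- exp(m)
  s <- e / rowSums(e)
  ad_node(s, list(x), function(g) list((g - rowSums(g * s)) * s))
}

# --- reductions -------------------------------------------------------------

ad_sum <- function(x) {
  x <- as_ad(x)
  ad_node(sum(x$value), list(x),
          function(g) list(array(as.numeric(g), dim(x$value) %||% length(x$value))))
}

ad_mean_all <- function(x) {
  x <- as_ad(x)
  n <- length(x$value)
  ad_node(mean(x$value), list(x),
          function(g) list(array(as.numeric(g) / n, dim(x$value) %||% n)))
}

# Mean over one axis of a 3-d or 4-d array; the axis is dropped.
ad_mean_axis <- function(x, axis) {
  x <- as_ad(x)
  d <- dim(x$value)
  keep <- setdiff(seq_along(d), axis)
  v <- apply(x$value, keep, mean)
  dim(v) <- d[keep]
  ad_node(v, list(x), function(g) {
    ge <- array(0, d[c(axis, keep)])
    ge[] <- rep(as.vector(g) / prod(d[axis]), each = prod(d[axis]))
    list(aperm(ge, order(c(axis, keep))))
  })
}

# --- normalization ----------------------------------------------------------

# Layer normalization over the last dim of a matrix (n, d), with affine.
ad_layernorm_rows <- function(x, gamma, beta, eps = 1e-6) {
  x <- as_ad(x); gamma <- as_ad(gamma); beta <- as_ad(beta)
  v <- x$value
  d <- ncol(v)
  mu <- rowMeans(v)
  xc <- v - mu
  varr <- rowMeans(xc * xc)
  inv <- 1 / sqrt(varr + eps)
  xhat <- xc * inv
  gv <- as.vector(gamma$value)
  out <- sweep(xhat, 2L, gv, "*")
  out <- sweep(out, 2L, as.vector(beta$value), "+")
  ad_node(out, list(x, gamma, beta), function(g) {
    dxhat <- sweep(g, 2L, gv, "*")
    dx <- (dxhat - rowMeans(dxhat) - xhat * rowMeans(dxhat * xhat)) * inv
    list(dx, colSums(g * xhat), colSums(g))
  })
}

# Batch normalization over channels (last dim) of a 4-d array (b, h, w, c)
# or matrix (n, c). `state` is an environment holding running_mean,
# running_var; updated in training mode with the given momentum.
ad_batchnorm <- function(x, gamma, beta, state, training = TRUE,
                         eps = 1e-5, momentum = 0.1) {
  x <- as_ad(x); gamma <- as_ad(gamma); beta <- as_ad(beta)
  v <- x$value
  d <- dim(v)
  cdim <- d[length(d)]
  per <- prod(d[-length(d)])
  xm <- matrix(v, nrow = per, ncol = cdim)
  gv <- as.vector(gamma$value); bv <- as.vector(beta$value)
  if (training) {
    mu <- colMeans(xm)
    xc <- sweep(xm, 2L, mu)
    varr <- colMeans(xc * xc)
    state$running_mean <- (1 - momentum) * state$running_mean + momentum * mu
    state$running_var <- (1 - momentum) * state$running_var + momentum * varr
  } else {
    mu <- state$running_mean
    xc <- sweep(xm, 2L, mu)
    varr <- state$running_var
  }
  inv <- 1 / sqrt(varr + eps)
  xhat <- sweep(xc, 2L, inv, "*")
  out <- sweep(sweep(xhat, 2L, gv, "*"), 2L, bv, "+")
  dim(out) <- d
  ad_node(out, list(x, gamma, beta), function(g) {
    gm <- matrix(g, nrow = per, ncol = cdim)
    dgamma <- colSums(gm * xhat)
    dbeta <- colSums(gm)
    dxhat <- sweep(gm, 2L, gv, "*")
    if (training) {
      dx <- sweep(dxhat - rep(colMeans(dxhat), each = per) -
                    xhat * rep(colMeans(dxhat * xhat), each = per),
                  2L, inv, "*")
    } else {
      dx <- sweep(dxhat, 2L, inv, "*")
    }
    dim(dx) <- d
    list(dx, dgamma, dbeta)
  })
}

# --- convolutions -----------------------------------------------------------

# Zero-pad the two spatial dims of (b, h, w, c).
pad_spatial <- function(v, ph, pw) {
  if (ph == 0L && pw == 0L) return(v)
  d <- dim(v)
  out <- array(0, c(d[1], d[2] + 2 * ph, d[3] + 2 * pw, d[4]))
  out[, ph + seq_len(d[2]), pw + seq_len(d[3]), ] <- v
  out
}

unpad_spatial <- function(v, ph, pw) {
  if (ph == 0L && pw == 0L) return(v)
  d <- dim(v)
  v[, ph + seq_len(d[2] - 2 * ph), pw + seq_len(d[3] - 2 * pw), , drop = FALSE]
}

# im2col index matrix for (h, w) spatial dims: returns an integer matrix of
# (ho*wo) x (kh*kw) linear indices into the padded h x w plane.
im2col_index <- function(h, w, kh, kw, sh, sw) {
  ho <- (h - kh) %/% sh + 1L
  wo <- (w - kw) %/% sw + 1L
  r0 <- (seq_len(ho) - 1L) * sh
  c0 <- (seq_len(wo) - 1L) * sw
  base <- outer(r0, c0 * h, "+") # ho x wo linear offsets (0-based), column-major (r, c)
  offs <- outer(seq_len(kh) - 1L, (seq_len(kw) - 1L) * h, "+")
  idx <- outer(as.vector(base), as.vector(offs), "+") + 1L
  list(idx = idx, ho = ho, wo = wo)
}

#' General 2-d convolution (channels-last), via im2col + BLAS
#'
#' @param x `(b, h, w, cin)` array or node.
#' @param w `(kh, kw, cin, cout)` kernel.
#' @param b length-`cout` bias or NULL.
#' @param stride integer stride (same in both dims).
#' @param padding `"valid"` or `"same"` (zero padding; `"same"` requires stride 1).
#' @keywords internal
ad_conv2d <- function(x, w, b = NULL, stride = 1L, padding = c("valid", "same")) {
  padding <- match.arg(padding)
  x <- as_ad(x); w <- as_ad(w)
  d <- dim(x$value)
  kd <- dim(w$value)
  kh <- kd[1]; kw <- kd[2]; cin <- kd[3]; cout <- kd[4]
  stopifnot(d[4] == cin)
  ph <- if (padding == "same") (kh - 1L) %/% 2L else 0L
  pw <- if (padding == "same") (kw - 1L) %/% 2L else 0L
  xp <- pad_spatial(x$value, ph, pw)
  dp <- dim(xp)
  ii <- im2col_index(dp[2], dp[3], kh, kw, stride, stride)
  bsz <- d[1]
  # xp (b, hp, wp, c) -> (b, hp*wp, c) -> gather -> (b, npos, k2, c)
  xr <- xp; dim(xr) <- c(bsz, dp[2] * dp[3], cin)
  cols <- xr[, as.vector(ii$idx), , drop = FALSE]
  dim(cols) <- c(bsz, nrow(ii$idx), ncol(ii$idx), cin)
  # rows iterate (b, position), columns iterate (kernel offset, cin); the same
  # column-major order flattens the kernel, so colm %*% wm is the convolution.
  colm <- matrix(cols, nrow = bsz * nrow(ii$idx), ncol = ncol(ii$idx) * cin)
  wm <- matrix(w$value, nrow = kh * kw * cin, ncol = cout)
  out <- colm %*% wm
  if (!is.null(b)) {
    b <- as_ad(b)
    out <- sweep(out, 2L, as.vector(b$value), "+")
  }
  ho <- ii$ho; wo <- ii$wo
  outa <- out; dim(outa) <- c(bsz, ho, wo, cout)
  parents <- if (is.null(b)) list(x, w) else list(x, w, b)
  node <- ad_node(outa, parents, function(g) {
    gm <- matrix(g, nrow = bsz * ho * wo, ncol = cout)
    gw <- crossprod(colm, gm)
    dim(gw) <- c(kh, kw, cin, cout)
    gcol <- gm %*% t(wm) # (b*npos) x (k2*cin)
    gxp <- array(0, c(bsz, dp[2] * dp[3], cin))
    gcola <- gcol; dim(gcola) <- c(bsz, ho * wo, kh * kw, cin)
    for (k in seq_len(kh * kw)) {
      tgt <- ii$idx[, k]
      gxp[, tgt, ] <- gxp[, tgt, , drop = FALSE] +
        array(gcola[, , k, , drop = FALSE], c(bsz, length(tgt), cin))
    }
    dim(gxp) <- dp
    gx <- unpad_spatial(gxp, ph, pw)
    gb <- if (is.null(b)) NULL else colSums(gm)
    if (is.null(b)) list(gx, gw) else list(gx, gw, gb)
  })
  node
}

#' Depthwise 2-d convolution ("same" padding, stride 1)
#'
#' One `kh x kw` spatial filter per channel, no cross-channel mixing.
#' Implemented by shift-and-accumulate over the kernel support.
#'
#' @param x `(b, h, w, c)` array or node.
#' @param w `(kh, kw, c)` kernel.
#' @param b length-`c` bias or NULL.
#' @keywords internal
ad_depthwise_conv2d <- function(x, w, b = NULL) {
  x <- as_ad(x); w <- as_ad(w)
  d <- dim(x$value)
  kd <- dim(w$value)
  kh <- kd[1]; kw <- kd[2]; cdim <- kd[3]
  stopifnot(d[4] == cdim)
  ph <- (kh - 1L) %/% 2L; pw <- (kw - 1L) %/% 2L
  xp <- pad_spatial(x$value, ph, pw)
  h <- d[2]; wdt <- d[3]
  out <- array(0, d)
  for (i in seq_len(kh)) {
    for (j in seq_len(kw)) {
      sl <- xp[, (i - 1L) + seq_len(h), (j - 1L) + seq_len(wdt), , drop = FALSE]
      wij <- rep(w$value[i, j, ], each = d[1] * h * wdt)
      out <- out + sl * wij
    }
  }
  if (!is.null(b)) {
    b <- as_ad(b)
    out <- out + rep(as.vector(b$value), each = d[1] * h * wdt)
  }
  parents <- if (is.null(b)) list(x, w) else list(x, w, b)
  ad_node(out, parents, function(g) {
    gp <- pad_spatial(g, ph, pw)
    gx <- array(0, d)
    gw <- array(0, kd)
    for (i in seq_len(kh)) {
      for (j in seq_len(kw)) {
        sl <- xp[, (i - 1L) + seq_len(h), (j - 1L) + seq_len(wdt), , drop = FALSE]
        gw[i, j, ] <- colSums(matrix(sl * g, ncol = cdim))
        gsl <- gp[, (kh - i) + seq_len(h), (kw - j) + seq_len(wdt), , drop = FALSE]
        gx <- gx + gsl * rep(w$value[i, j, ], each = d[1] * h * wdt)
      }
    }
    gb <- if (is.null(b)) NULL else colSums(matrix(g, ncol = cdim))
    if (is.null(b)) list(gx, gw) else list(gx, gw, gb)
  })
}

# --- losses -----------------------------------------------------------------

# Mean categorical cross-entropy from logits (n, k) against one-hot (n, k).
ad_softmax_crossentropy <- function(logits, y_onehot) {
  logits <- as_ad(logits)
  v <- logits$value
  n <- nrow(v)
  m <- v - apply(v, 1L, max)
  lse <- log(rowSums(exp(m)))
  logp <- m - lse
  loss <- -sum(y_onehot * logp) / n
  p <- exp(logp)
  ad_node(loss, list(logits), function(g) list(as.numeric(g) * (p - y_onehot) / n))
}

# Mean binary cross-entropy from a single logit column (n, 1) against y in {0,1}.
ad_sigmoid_bce <- function(logits, y) {
  logits <- as_ad(logits)
  v <- as.vector(logits$value)
  n <- length(v)
  p <- 1 / (1 + exp(-v))
  loss <- -mean(y * log(pmax(p, 1e-12)) + (1 - y) * log(pmax(1 - p, 1e-12)))
  ad_node(loss, list(logits), function(g) {
    gv <- as.numeric(g) * (p - y) / n
    dim(gv) <- dim(logits$value)
    list(gv)
  })
}

# --- composite ops used by the model builders -------------------------------

# Multiply by a scalar parameter.
ad_mul_scalar <- function(x, s) {
  x <- as_ad(x); s <- as_ad(s)
  sv <- as.numeric(s$value)
  ad_node(x$value * sv, list(x, s),
          function(g) list(g * sv, sum(g * x$value)))
}

# Column gather on a matrix (n, m) by an index vector (typically a
# permutation, e.g. patch extraction); backward scatter-adds.
ad_index_cols <- function(x, idx) {
  x <- as_ad(x)
  m <- ncol(x$value)
  unique_idx <- anyDuplicated(idx) == 0L
  ad_node(x$value[, idx, drop = FALSE], list(x), function(g) {
    gx <- matrix(0, nrow(g), m)
    if (unique_idx) {
      gx[, idx] <- g
    } else {
      for (k in seq_along(idx)) gx[, idx[k]] <- gx[, idx[k]] + g[, k]
    }
    list(gx)
  })
}

# Add a (n, d) parameter (e.g. positional embedding) to every slice of a
# (b, n, d) activation.
ad_add_bcast_first <- function(x, p) {
  x <- as_ad(x); p <- as_ad(p)
  d <- dim(x$value)
  ad_node(x$value + rep(as.vector(p$value), each = d[1]), list(x, p), function(g) {
    gp <- colSums(matrix(g, nrow = d[1]))
    dim(gp) <- dim(p$value)
    list(g, gp)
  })
}

# Batched multi-head scaled dot-product attention core.
# q, k, v: (b*n, heads*kd) matrices (token-major within batch: row = (batch,
# token) with batch fastest). Returns the concatenated head outputs in the
# same layout. Softmax row sums are exact by construction.
ad_attention_core <- function(q, k, v, n_tokens, n_heads, key_dim, batch) {
  q <- as_ad(q); k <- as_ad(k); v <- as_ad(v)
  hk <- n_heads * key_dim
  out <- matrix(0, batch * n_tokens, hk)
  attn <- vector("list", batch * n_heads)
  rows_of <- function(ib) seq.int(ib, by = batch, length.out = n_tokens)
  cols_of <- function(ih) (ih - 1L) * key_dim + seq_len(key_dim)
  for (ib in seq_len(batch)) {
    rws <- rows_of(ib)
    for (ih in seq_len(n_heads)) {
      cls <- cols_of(ih)
      Qm <- q$value[rws, cls, drop = FALSE]
      Km <- k$value[rws, cls, drop = FALSE]
      Vm <- v$value[rws, cls, drop = FALSE]
      S <- Qm %*% t(Km) / sqrt(key_dim)
      S <- S - apply(S, 1L, max)
      A <- exp(S); A <- A / rowSums(A)
      attn[[(ib - 1L) * n_heads + ih]] <- A
      out[rws, cls] <- A %*% Vm
    }
  }
  ad_node(out, list(q, k, v), function(g) {
    gq <- matrix(0, nrow(g), hk); gk <- gq; gv <- gq
    for (ib in seq_len(batch)) {
      rws <- rows_of(ib)
      for (ih in seq_len(n_heads)) {
        cls <- cols_of(ih)
        A <- attn[[(ib - 1L) * n_heads + ih]]
        Qm <- q$value[rws, cls, drop = FALSE]
        Km <- k$value[rws, cls, drop = FALSE]
        Vm <- v$value[rws, cls, drop = FALSE]
        gO <- g[rws, cls, drop = FALSE]
        gA <- gO %*% t(Vm)
        gS <- (gA - rowSums(gA * A)) * A / sqrt(key_dim)
        gq[rws, cls] <- gS %*% Km
        gk[rws, cls] <- t(gS) %*% Qm
        gv[rws, cls] <- t(A) %*% gO
      }
    }
    list(gq, gk, gv)
  })
}

# Map-weighted spatial pooling (adaptive tokenization): x (b, h, w, c),
# alpha (b, h, w, s) -> tokens (b, s, c); token_s = mean_{hw}(x * alpha_s).
ad_map_pool <- function(x, alpha) {
  x <- as_ad(x); alpha <- as_ad(alpha)
  d <- dim(x$value); s <- dim(alpha$value)[4]
  npix <- d[2] * d[3]
  out <- array(0, c(d[1], s, d[4]))
  for (ib in seq_len(d[1])) {
    Xm <- matrix(x$value[ib, , , ], npix, d[4])
    Am <- matrix(alpha$value[ib, , , ], npix, s)
    out[ib, , ] <- crossprod(Am, Xm) / npix
  }
  ad_node(out, list(x, alpha), function(g) {
    gx <- array(0, d); ga <- array(0, dim(alpha$value))
    for (ib in seq_len(d[1])) {
      Xm <- matrix(x$value[ib, , , ], npix, d[4])
      Am <- matrix(alpha$value[ib, , , ], npix, s)
      gz <- matrix(g[ib, , ], s, d[4])
      gx[ib, , , ] <- array(Am %*% gz / npix, c(d[2], d[3], d[4]))
      ga[ib, , , ] <- array(Xm %*% t(gz) / npix, c(d[2], d[3], s))
    }
    list(gx, ga)
  })
}
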