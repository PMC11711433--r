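# The four model families: compact ViT, TokenLearner, ConvMixer, and the
# TokenMixer hybrid, plus the patch/attention/tokenization primitives they
# are assembled from and exact trainable-parameter accounting.

# --- patch arithmetic -------------------------------------------------------

#' Number of non-overlapping patches of an image
#'
#' For an `H x W` image cut into non-overlapping square patches of side `P`,
#' the patch count is `N = H * W / P^2`.
#'
#' @param H,W image height and width in pixels.
#' @param P patch side in pixels; must divide both `H` and `W`.
#' @return integer patch count.
#' @export
#' @examples
#' compute_num_patches(224, 224, 14) # 256
compute_num_patches <- function(H, W, P) {
  if (P <= 0 || H %% P != 0 || W %% P != 0) {
    stop("patch size ", P, " must divide image dims ", H, "x", W)
  }
  as.integer(H * W / P^2)
}

# Linear indices (into the column-major (H, W, C) array) that pull out the
# flattened patches. `grid = "row"` enumerates patches row-by-row (the
# documented PatchGrid order); `grid = "col"` is the R-native order used
# internally so that reshaping a token sequence recovers the spatial grid.
patch_index <- function(H, W, C, P, grid = c("row", "col")) {
  grid <- match.arg(grid)
  gh <- H %/% P; gw <- W %/% P
  within <- as.vector(outer(seq_len(P), H * (seq_len(P) - 1L), "+"))
  within <- as.vector(outer(within, H * W * (seq_len(C) - 1L), "+"))
  if (grid == "row") {
    pc <- rep(seq_len(gw), times = gh)
    pr <- rep(seq_len(gh), each = gw)
  } else {
    pr <- rep(seq_len(gh), times = gw)
    pc <- rep(seq_len(gw), each = gh)
  }
  base <- (pr - 1L) * P + H * P * (pc - 1L)
  idx <- outer(within, base, "+") # (P*P*C, N)
  idx
}

#' Decompose an image into flattened non-overlapping patches
#'
#' @param image `(H, W, C)` numeric array; `P` must divide both spatial dims.
#' @param P patch side in pixels.
#' @return a `patch_grid` object: list with `H`, `W`, `C`, `P`, `N` and
#'   `patches`, an `(N, P*P*C)` matrix in row-major grid order.
#' @export
extract_patches <- function(image, P) {
  d <- dim(image)
  if (length(d) != 3L) stop("image must be a rank-3 (H, W, C) array")
  N <- compute_num_patches(d[1], d[2], P)
  idx <- patch_index(d[1], d[2], d[3], P, grid = "row")
  patches <- matrix(as.vector(image)[as.vector(idx)], ncol = N)
  structure(list(H = d[1], W = d[2], C = d[3], P = as.integer(P), N = N,
                 patches = t(patches)),
            class = "patch_grid")
}

#' Reassemble an image from a patch grid
#'
#' Exact inverse of [extract_patches()].
#' @param grid a `patch_grid` object.
#' @return the `(H, W, C)` array.
#' @export
reassemble_patches <- function(grid) {
  idx <- patch_index(grid$H, grid$W, grid$C, grid$P, grid = "row")
  out <- numeric(grid$H * grid$W * grid$C)
  out[as.vector(idx)] <- as.vector(t(grid$patches))
  array(out, c(grid$H, grid$W, grid$C))
}

# --- attention primitives (functional forms) --------------------------------

#' Scaled dot-product attention
#'
#' `softmax(Q K' / sqrt(d_k)) V`, with the softmax taken row-wise over the
#' score matrix. Every output row is a convex combination of the rows of `V`.
#'
#' @param Q,K,V numeric matrices; `Q` and `K` share their column dimension,
#'   `K` and `V` share their row dimension.
#' @param d_k key dimension used in the scaling factor (defaults to `ncol(K)`).
#' @return `nrow(Q) x ncol(V)` matrix.
#' @export
scaled_dot_attention <- function(Q, K, V, d_k = ncol(K)) {
  if (d_k <= 0) stop("d_k must be positive")
  if (ncol(Q) != ncol(K)) stop("Q and K must share their trailing dimension")
  if (nrow(K) != nrow(V)) stop("K and V must share their leading dimension")
  S <- Q %*% t(K) / sqrt(d_k)
  S <- S - apply(S, 1L, max)
  A <- exp(S)
  A <- A / rowSums(A)
  A %*% V
}

#' Initialize multi-head attention projection weights
#'
#' @param d token dimension; @param n_heads number of heads;
#' @param key_dim per-head query/key/value dimension.
#' @param seed integer seed; with `zero = TRUE` all weights are zero.
#' @return named list of projection matrices and biases.
#' @export
multi_head_attention_weights <- function(d, n_heads, key_dim = d %/% n_heads,
                                         seed = 1L, zero = FALSE) {
  hk <- n_heads * key_dim
  if (zero) {
    mk <- function(r, c) matrix(0, r, c)
  } else {
    set.seed(seed)
    mk <- function(r, c) glorot_uniform(c(r, c), r, c)
  }
  list(Wq = mk(d, hk), bq = numeric(hk),
       Wk = mk(d, hk), bk = numeric(hk),
       Wv = mk(d, hk), bv = numeric(hk),
       Wo = mk(hk, d), bo = numeric(d))
}

#' Multi-head self-attention over a token matrix
#'
#' Projects tokens to per-head queries/keys/values, applies
#' [scaled_dot_attention()] per head, concatenates the head outputs and
#' projects back to the token dimension. Output shape equals input shape.
#'
#' @param X `(n_tokens, d)` matrix.
#' @param n_heads number of attention heads (> 0).
#' @param key_dim per-head dimension (default `d / n_heads`).
#' @param weights projection weights from [multi_head_attention_weights()].
#' @return `(n_tokens, d)` matrix.
#' @export
multi_head_attention <- function(X, n_heads, key_dim = ncol(X) %/% n_heads,
                                 weights = multi_head_attention_weights(ncol(X), n_heads, key_dim)) {
  if (n_heads <= 0) stop("n_heads must be positive")
  d <- ncol(X)
  Q <- sweep(X %*% weights$Wq, 2L, weights$bq, "+")
  K <- sweep(X %*% weights$Wk, 2L, weights$bk, "+")
  V <- sweep(X %*% weights$Wv, 2L, weights$bv, "+")
  out <- matrix(0, nrow(X), n_heads * key_dim)
  for (h in seq_len(n_heads)) {
    cls <- (h - 1L) * key_dim + seq_len(key_dim)
    out[, cls] <- scaled_dot_attention(Q[, cls, drop = FALSE],
                                       K[, cls, drop = FALSE],
                                       V[, cls, drop = FALSE], d_k = key_dim)
  }
  sweep(out %*% weights$Wo, 2L, weights$bo, "+")
}

#' Initialize the weights of one pre-norm encoder block
#'
#' @inheritParams multi_head_attention_weights
#' @param mlp_hidden hidden width of the block's two-layer GELU MLP.
#' @param zero_residual zero the attention output and MLP weights so the
#'   block reduces to the identity (residual path only).
#' @export
encoder_block_weights <- function(d, n_heads, key_dim = d %/% n_heads,
                                  mlp_hidden = 2L * d, seed = 1L,
                                  zero_residual = FALSE) {
  set.seed(seed)
  w <- list(
    ln1_gamma = rep(1, d), ln1_beta = numeric(d),
    mha = multi_head_attention_weights(d, n_heads, key_dim, seed = seed + 1L),
    ln2_gamma = rep(1, d), ln2_beta = numeric(d),
    W1 = glorot_uniform(c(d, mlp_hidden), d, mlp_hidden), b1 = numeric(mlp_hidden),
    W2 = glorot_uniform(c(mlp_hidden, d), mlp_hidden, d), b2 = numeric(d)
  )
  if (zero_residual) {
    w$mha$Wo[] <- 0
    w$W2[] <- 0
  }
  w
}

#' Pre-norm transformer encoder block (functional form)
#'
#' `X + MHA(LN(X))`, then `Y + MLP(LN(Y))` with a two-layer GELU MLP; shape
#' preserved.
#'
#' @param X `(n_tokens, d)` matrix.
#' @param n_heads,key_dim attention geometry.
#' @param weights from [encoder_block_weights()].
#' @return `(n_tokens, d)` matrix.
#' @export
transformer_encoder_block <- function(X, n_heads, key_dim = ncol(X) %/% n_heads,
                                      weights = encoder_block_weights(ncol(X), n_heads, key_dim)) {
  ln <- function(x, g, b) {
    mu <- rowMeans(x); xc <- x - mu
    inv <- 1 / sqrt(rowMeans(xc * xc) + 1e-6)
    sweep(sweep(xc * inv, 2L, g, "*"), 2L, b, "+")
  }
  a <- multi_head_attention(ln(X, weights$ln1_gamma, weights$ln1_beta),
                            n_heads, key_dim, weights$mha)
  Y <- X + a
  h <- ln(Y, weights$ln2_gamma, weights$ln2_beta) %*% weights$W1
  h <- sweep(h, 2L, weights$b1, "+")
  h <- h * stats::pnorm(h)
  Y + sweep(h %*% weights$W2, 2L, weights$b2, "+")
}

# --- adaptive tokenization (functional forms) -------------------------------

#' Adaptive tokenization from spatial attention maps
#'
#' Each token is the spatial global average of the frame multiplied
#' elementwise (Hadamard product) by one attention map broadcast over
#' channels: `z_i = GlobalAvgPool(X * broadcast(alpha_i))`.
#'
#' @param x `(H, W, C)` frame.
#' @param alpha `(H, W, S)` attention maps (already through their bounded
#'   activation, values in `[0, 1]`).
#' @return `(S, C)` token matrix.
#' @export
token_learner_tokenize <- function(x, alpha) {
  d <- dim(x); da <- dim(alpha)
  if (length(da) != 3L || any(da[1:2] != d[1:2])) stop("alpha must be (H, W, S)")
  S <- da[3]
  if (S <= 0) stop("need at least one attention map")
  Xm <- matrix(x, d[1] * d[2], d[3])
  Am <- matrix(alpha, d[1] * d[2], S)
  crossprod(Am, Xm) / (d[1] * d[2])
}

#' Weights for the attention-map tokenizer
#'
#' Layer normalization, an optional depthwise mixing stage (the TokenMixer
#' refinement), and four map-generating convolutions (bias-free; GELU on the
#' first three, sigmoid on the last).
#'
#' @param c_dim channel dim of the token grid the tokenizer operates on.
#' @param config a [tokenmixer_config()] (or tokenlearner config) supplying
#'   `num_tokens`, `map_kernel`, and (for the hybrid) `depthwise_kernel` /
#'   `depthwise_channels`.
#' @param seed integer seed; `zero_maps = TRUE` zeroes the map convolutions.
#' @export
attention_map_tokenizer_weights <- function(c_dim, config, seed = 1L, zero_maps = FALSE) {
  set.seed(seed)
  S <- config$num_tokens
  k <- config$map_kernel
  mk <- function(dims, fi, fo) if (zero_maps) array(0, dims) else glorot_uniform(dims, fi, fo)
  w <- list(
    ln_gamma = rep(1, c_dim), ln_beta = numeric(c_dim),
    conv1 = mk(c(k, k, c_dim, S), k * k * c_dim, S),
    conv2 = mk(c(k, k, S, S), k * k * S, S),
    conv3 = mk(c(k, k, S, S), k * k * S, S),
    conv4 = mk(c(k, k, S, S), k * k * S, S)
  )
  if (!is.null(config$depthwise_kernel)) {
    dk <- config$depthwise_kernel
    dc <- config$depthwise_channels
    w$depthwise <- glorot_uniform(c(dk, dk, dc), dk * dk, dk * dk)
    w$depthwise_bias <- numeric(dc)
    w$bn_gamma <- rep(1, dc)
    w$bn_beta <- numeric(dc)
  }
  w
}

#' Attention-map tokenizer over an embedded token grid (functional form)
#'
#' Normalizes the grid, optionally applies the hybrid's partial depthwise
#' convolution + batch normalization (inference mode, identity statistics),
#' generates `S` spatial attention maps through four convolutions with a
#' sigmoid on the last, and pools the Hadamard product of maps and input
#' into `S` tokens.
#'
#' @param x `(H, W, C)` token grid (one frame).
#' @param config tokenizer configuration (see
#'   [attention_map_tokenizer_weights()]).
#' @param weights tokenizer weights.
#' @return `(S, C)` token matrix.
#' @export
attention_map_tokenizer <- function(x, config,
                                    weights = attention_map_tokenizer_weights(dim(x)[3], config)) {
  if (config$num_tokens <= 0) stop("num_tokens must be positive")
  d <- dim(x)
  xb <- array(x, c(1, d))
  x2 <- matrix(x, d[1] * d[2], d[3])
  mu <- rowMeans(x2); xc <- x2 - mu
  inv <- 1 / sqrt(rowMeans(xc * xc) + 1e-6)
  normed <- sweep(sweep(xc * inv, 2L, weights$ln_gamma, "*"), 2L, weights$ln_beta, "+")
  h <- array(normed, c(1, d))
  if (!is.null(weights$depthwise)) {
    dc <- config$depthwise_channels
    part <- h[, , , seq_len(dc), drop = FALSE]
    mixed <- ad_value(ad_depthwise_conv2d(part, weights$depthwise, weights$depthwise_bias))
    # inference-mode batch normalization with identity statistics
    mixed <- sweep(sweep(mixed, 4L, weights$bn_gamma / sqrt(1 + 1e-5), "*"),
                   4L, weights$bn_beta, "+")
    h[, , , seq_len(dc)] <- mixed
  }
  gelu <- function(v) v * stats::pnorm(v)
  a <- gelu(ad_value(ad_conv2d(h, weights$conv1, NULL, 1L, "same")))
  a <- gelu(ad_value(ad_conv2d(a, weights$conv2, NULL, 1L, "same")))
  a <- gelu(ad_value(ad_conv2d(a, weights$conv3, NULL, 1L, "same")))
  a <- ad_value(ad_conv2d(a, weights$conv4, NULL, 1L, "same"))
  alpha <- 1 / (1 + exp(-a))
  token_learner_tokenize(x, array(alpha[1, , , ], c(d[1], d[2], config$num_tokens)))
}

# --- ConvMixer primitives (functional forms) --------------------------------

#' Weights for the ConvMixer stem / one mixer block
#' @param config a [convmixer_config()].
#' @param seed integer seed; `zero = TRUE` gives all-zero kernels and biases.
#' @export
convmixer_weights <- function(config, seed = 1L, zero = FALSE) {
  set.seed(seed)
  h <- config$width; p <- config$patch; k <- config$kernel
  mk <- function(dims, fi, fo) if (zero) array(0, dims) else glorot_uniform(dims, fi, fo)
  list(
    stem_kernel = mk(c(p, p, 3, h), p * p * 3, h), stem_bias = numeric(h),
    stem_bn_gamma = rep(1, h), stem_bn_beta = numeric(h),
    dw_kernel = mk(c(k, k, h), k * k, k * k), dw_bias = numeric(h),
    bn1_gamma = rep(1, h), bn1_beta = numeric(h),
    pw_kernel = mk(c(1, 1, h, h), h, h), pw_bias = numeric(h),
    bn2_gamma = rep(1, h), bn2_beta = numeric(h)
  )
}

# inference-mode batch norm with identity statistics (mean 0, var 1)
bn_identity <- function(v, gamma, beta, eps = 1e-5) {
  d <- dim(v)
  per <- prod(d[-length(d)])
  out <- sweep(sweep(matrix(v, per), 2L, gamma / sqrt(1 + eps), "*"), 2L, beta, "+")
  dim(out) <- d
  out
}

#' ConvMixer patch-embedding stem (functional form)
#'
#' Convolution with kernel = stride = `p` mapping 3 channels to width `h`,
#' then GELU, then batch normalization (inference mode, identity statistics):
#' `Z0 = BN(GELU(Conv(X)))`.
#'
#' @param x `(H, W, 3)` image or `(b, H, W, 3)` batch; `p` must divide the
#'   spatial dims.
#' @param config a [convmixer_config()].
#' @param weights from [convmixer_weights()].
#' @return `(H/p, W/p, h)` feature map (or batch thereof).
#' @export
convmixer_stem <- function(x, config, weights = convmixer_weights(config)) {
  d <- dim(x)
  single <- length(d) == 3L
  if (single) { x <- array(x, c(1, d)); d <- dim(x) }
  if (d[2] %% config$patch != 0 || d[3] %% config$patch != 0) {
    stop("stem patch size must divide the spatial dims")
  }
  z <- ad_value(ad_conv2d(x, weights$stem_kernel, weights$stem_bias,
                          stride = config$patch, padding = "valid"))
  z <- z * stats::pnorm(z)
  z <- bn_identity(z, weights$stem_bn_gamma, weights$stem_bn_beta)
  if (single) array(z, dim(z)[-1]) else z
}

#' One ConvMixer block (functional form)
#'
#' Depthwise stage `Z' = BN(GELU(DepthwiseConv(Z)) + Z)` followed by the
#' pointwise stage `BN(GELU(PointwiseConv(Z')))`; the residual is added
#' before the first batch normalization. Spatial dims and channels preserved.
#'
#' @param z `(n, n, h)` feature map or `(b, n, n, h)` batch.
#' @inheritParams convmixer_stem
#' @export
convmixer_block <- function(z, config, weights = convmixer_weights(config)) {
  d <- dim(z)
  single <- length(d) == 3L
  if (single) { z <- array(z, c(1, d)); d <- dim(z) }
  if (d[4] != config$width) stop("channel count must equal the mixer width h")
  gelu <- function(v) v * stats::pnorm(v)
  dw <- ad_value(ad_depthwise_conv2d(z, weights$dw_kernel, weights$dw_bias))
  zp <- bn_identity(gelu(dw) + z, weights$bn1_gamma, weights$bn1_beta)
  pw <- ad_value(ad_conv2d(zp, weights$pw_kernel, weights$pw_bias, 1L, "valid"))
  out <- bn_identity(gelu(pw), weights$bn2_gamma, weights$bn2_beta)
  if (single) array(out, dim(out)[-1]) else out
}
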