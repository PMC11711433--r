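# Parameterized layers on top of the autodiff engine.
#
# A model is assembled from layer objects; each layer registers its trainable
# arrays in a shared parameter store so the per-layer inventory (and therefore
# the exact trainable-parameter count) falls out of construction.

new_param_store <- function() {
  ps <- new.env(parent = emptyenv())
  ps$params <- list()
  ps$inventory <- list()
  ps
}

store_param <- function(ps, name, value) {
  node <- ad_param(value)
  ps$params[[name]] <- node
  ps$inventory[[name]] <- length(value)
  node
}

glorot_uniform <- function(dims, fan_in, fan_out) {
  lim <- sqrt(6 / (fan_in + fan_out))
  array(stats::runif(prod(dims), -lim, lim), dims)
}

# Fully connected layer: (n, d_in) -> (n, d_out).
layer_dense <- function(ps, name, d_in, d_out) {
  W <- store_param(ps, paste0(name, ".kernel"), glorot_uniform(c(d_in, d_out), d_in, d_out))
  b <- store_param(ps, paste0(name, ".bias"), numeric(d_out))
  function(x) ad_add_rowvec(ad_matmul(x, W), b)
}

# Layer normalization over the trailing feature dim of a (n, d) matrix.
layer_layernorm <- function(ps, name, d) {
  g <- store_param(ps, paste0(name, ".gamma"), rep(1, d))
  b <- store_param(ps, paste0(name, ".beta"), numeric(d))
  function(x) ad_layernorm_rows(x, g, b)
}

# Batch normalization over the channel (last) dim; scale and shift are
# trainable, running statistics are state (not counted).
layer_batchnorm <- function(ps, name, c_dim) {
  g <- store_param(ps, paste0(name, ".gamma"), rep(1, c_dim))
  b <- store_param(ps, paste0(name, ".beta"), numeric(c_dim))
  st <- new.env(parent = emptyenv())
  st$running_mean <- numeric(c_dim)
  st$running_var <- rep(1, c_dim)
  function(x, training = FALSE) ad_batchnorm(x, g, b, st, training = training)
}

# Standard 2-d convolution, channels-last.
layer_conv2d <- function(ps, name, kernel, c_in, c_out, stride = 1L,
                         padding = "valid", use_bias = TRUE) {
  fan_in <- kernel * kernel * c_in
  W <- store_param(ps, paste0(name, ".kernel"),
                   glorot_uniform(c(kernel, kernel, c_in, c_out), fan_in, c_out))
  b <- if (use_bias) store_param(ps, paste0(name, ".bias"), numeric(c_out)) else NULL
  function(x) ad_conv2d(x, W, b, stride = stride, padding = padding)
}

# Depthwise 2-d convolution ("same", stride 1), one filter per channel.
layer_depthwise <- function(ps, name, kernel, c_dim, use_bias = TRUE) {
  W <- store_param(ps, paste0(name, ".depthwise_kernel"),
                   glorot_uniform(c(kernel, kernel, c_dim), kernel * kernel, kernel * kernel))
  b <- if (use_bias) store_param(ps, paste0(name, ".bias"), numeric(c_dim)) else NULL
  function(x) ad_depthwise_conv2d(x, W, b)
}

# Trainable input standardization: per-channel shift and scale plus a global
# gain, initialized to the identity (7 parameters for RGB input).
layer_input_standardize <- function(ps, name = "input_standardize", channels = 3L) {
  shift <- store_param(ps, paste0(name, ".shift"), numeric(channels))
  scale <- store_param(ps, paste0(name, ".scale"), rep(1, channels))
  gain <- store_param(ps, paste0(name, ".gain"), 1)
  function(x) {
    shifted <- ad_add_channel(x, shift)
    scaled <- ad_mul_channel(shifted, scale)
    ad_mul_scalar(scaled, gain)
  }
}

# Channel-wise multiply of an array (..., C) by a length-C vector parameter.
ad_mul_channel <- function(x, v) {
  x <- as_ad(x); v <- as_ad(v)
  d <- dim(x$value)
  cdim <- d[length(d)]
  per <- prod(d[-length(d)])
  vv <- rep(as.vector(v$value), each = per)
  ad_node(x$value * vv, list(x, v), function(g) {
    list(g * vv, colSums(matrix(g * x$value, nrow = per, ncol = cdim)))
  })
}

# Learned positional embedding over a fixed token count.
layer_pos_embedding <- function(ps, name, n_tokens, d) {
  P <- store_param(ps, paste0(name, ".embedding"),
                   array(stats::rnorm(n_tokens * d, sd = 0.02), c(n_tokens, d)))
  function(x) ad_add_bcast_first(x, P)
}

# Multi-head self-attention over a (b, n, d) activation.
layer_mha <- function(ps, name, d, n_heads, key_dim) {
  hk <- n_heads * key_dim
  dq <- layer_dense(ps, paste0(name, ".query"), d, hk)
  dk <- layer_dense(ps, paste0(name, ".key"), d, hk)
  dv <- layer_dense(ps, paste0(name, ".value"), d, hk)
  dout <- layer_dense(ps, paste0(name, ".out"), hk, d)
  function(x3, batch, n_tokens) {
    x2 <- ad_reshape(x3, c(batch * n_tokens, d))
    att <- ad_attention_core(dq(x2), dk(x2), dv(x2),
                             n_tokens = n_tokens, n_heads = n_heads,
                             key_dim = key_dim, batch = batch)
    ad_reshape(dout(att), c(batch, n_tokens, d))
  }
}

# Pre-norm transformer encoder block: LN -> MHA -> add, LN -> MLP(GELU) -> add.
layer_encoder_block <- function(ps, name, d, n_heads, key_dim, mlp_hidden) {
  ln1 <- layer_layernorm(ps, paste0(name, ".ln1"), d)
  mha <- layer_mha(ps, paste0(name, ".mha"), d, n_heads, key_dim)
  ln2 <- layer_layernorm(ps, paste0(name, ".ln2"), d)
  fc1 <- layer_dense(ps, paste0(name, ".mlp1"), d, mlp_hidden)
  fc2 <- layer_dense(ps, paste0(name, ".mlp2"), mlp_hidden, d)
  function(x3, batch, n_tokens) {
    x2 <- ad_reshape(x3, c(batch * n_tokens, d))
    normed <- ad_reshape(ln1(x2), c(batch, n_tokens, d))
    x3 <- ad_add(x3, mha(normed, batch, n_tokens))
    x2 <- ad_reshape(x3, c(batch * n_tokens, d))
    h <- fc2(ad_gelu(fc1(ln2(x2))))
    ad_add(x3, ad_reshape(h, c(batch, n_tokens, d)))
  }
}
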