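# Patch arithmetic, attention and tokenization primitives, the ConvMixer
# stages, and the four builders with their exact parameter inventories.

test_that("patch count follows the division rule", {
  expect_equal(compute_num_patches(224, 224, 14), 256L)
  expect_equal(compute_num_patches(14, 14, 14), 1L)
  expect_error(compute_num_patches(224, 224, 15), "divide")
})

test_that("patch extraction flattens, counts and inverts exactly", {
  img <- tiny_image(224, 224, seed = 3)
  g <- extract_patches(img, 14)
  expect_equal(g$N, 256L)
  expect_equal(dim(g$patches), c(256L, 14L * 14L * 3L))
  expect_equal(reassemble_patches(g), img)
  one <- tiny_image(6, 6, seed = 4)
  g1 <- extract_patches(one, 6)
  expect_equal(as.vector(g1$patches[1, ]), as.vector(one))
  # row-major order: second patch of a 2x2 grid is the top-right block
  quad <- tiny_image(8, 8, seed = 5)
  g2 <- extract_patches(quad, 4)
  expect_equal(array(g2$patches[2, ], c(4, 4, 3)), quad[1:4, 5:8, ])
})

test_that("scaled dot-product attention matches hand and brute-force values", {
  expect_equal(scaled_dot_attention(matrix(c(1, 0), 1), matrix(c(1, 0), 1),
                                    matrix(c(1, 0), 1)),
               matrix(c(1, 0), 1))
  # identical keys: uniform weights, every output row is the mean of V rows
  K <- matrix(1, 3, 2)
  V <- matrix(rnorm(6), 3, 2)
  out <- scaled_dot_attention(matrix(rnorm(4), 2, 2), K, V)
  expect_equal(out[1, ], colMeans(V), tolerance = 1e-12)
  expect_equal(out[2, ], colMeans(V), tolerance = 1e-12)
  # frozen two-key example: scores (1/sqrt(2), 0) -> softmax -> (0.6698, 0.3302)
  out2 <- scaled_dot_attention(matrix(c(1, 0), 1), diag(2), diag(2), d_k = 2)
  expect_equal(round(out2, 4), matrix(c(0.6698, 0.3302), 1))
  expect_error(scaled_dot_attention(diag(2), diag(2), diag(2), d_k = 0), "positive")
  set.seed(31)
  for (i in 1:100) {
    nq <- sample(1:4, 1); nk <- sample(1:4, 1); d <- sample(1:4, 1); dv <- sample(1:4, 1)
    Q <- matrix(rnorm(nq * d), nq); K <- matrix(rnorm(nk * d), nk)
    V <- matrix(rnorm(nk * dv), nk)
    expect_lt(max(abs(scaled_dot_attention(Q, K, V) - brute_attention(Q, K, V, d))), 1e-10)
  }
})

test_that("attention outputs stay in the convex hull of V and rows normalize", {
  set.seed(77)
  for (i in 1:20) {
    Q <- matrix(rnorm(8), 4, 2); K <- matrix(rnorm(6), 3, 2)
    # V = identity exposes the softmax weights directly
    W <- scaled_dot_attention(Q, K, diag(3))
    expect_lt(max(abs(rowSums(W) - 1)), 1e-6)
    expect_true(all(W >= 0))
  }
})

brute_mha <- function(X, n_heads, key_dim, w) {
  Q <- sweep(X %*% w$Wq, 2, w$bq, "+")
  K <- sweep(X %*% w$Wk, 2, w$bk, "+")
  V <- sweep(X %*% w$Wv, 2, w$bv, "+")
  heads <- lapply(seq_len(n_heads), function(h) {
    cls <- (h - 1) * key_dim + seq_len(key_dim)
    brute_attention(Q[, cls, drop = FALSE], K[, cls, drop = FALSE],
                    V[, cls, drop = FALSE], key_dim)
  })
  sweep(do.call(cbind, heads) %*% w$Wo, 2, w$bo, "+")
}

test_that("multi-head attention preserves shape and matches brute force", {
  X <- matrix(rnorm(256 * 64), 256, 64)
  w <- multi_head_attention_weights(64, 4, 16, seed = 9)
  out <- multi_head_attention(X, 4, 16, w)
  expect_equal(dim(out), dim(X))
  expect_error(multi_head_attention(X, 0), "positive")
  # single head with identity projections reduces to scaled_dot_attention
  wi <- multi_head_attention_weights(4, 1, 4, zero = TRUE)
  wi$Wq <- wi$Wk <- wi$Wv <- wi$Wo <- diag(4)
  Xs <- matrix(rnorm(12), 3, 4)
  expect_equal(multi_head_attention(Xs, 1, 4, wi),
               scaled_dot_attention(Xs, Xs, Xs), tolerance = 1e-12)
  set.seed(41)
  for (i in 1:100) {
    n <- sample(1:4, 1); hH <- sample(1:2, 1); kd <- sample(1:3, 1); d <- 4
    Xr <- matrix(rnorm(n * d), n, d)
    wr <- multi_head_attention_weights(d, hH, kd, seed = 100 + i)
    expect_lt(max(abs(multi_head_attention(Xr, hH, kd, wr) -
                        brute_mha(Xr, hH, kd, wr))), 1e-5)
  }
})

test_that("encoder block is the identity under zeroed residual branches", {
  X <- matrix(rnorm(5 * 8), 5, 8)
  wz <- encoder_block_weights(8, 2, 4, zero_residual = TRUE)
  expect_equal(transformer_encoder_block(X, 2, 4, wz), X, tolerance = 1e-12)
  w <- encoder_block_weights(8, 2, 4, seed = 5)
  out1 <- transformer_encoder_block(X, 2, 4, w)
  expect_equal(dim(out1), dim(X))
  # fixed weights, fixed input: two stacked applications are bit-stable
  a <- transformer_encoder_block(transformer_encoder_block(X, 2, 4, w), 2, 4, w)
  b <- transformer_encoder_block(transformer_encoder_block(X, 2, 4, w), 2, 4, w)
  expect_identical(a, b)
})

test_that("token generation obeys the Hadamard-pool identities", {
  x <- tiny_image(6, 5, seed = 11)
  x[, , ] <- array(rnorm(6 * 5 * 3), c(6, 5, 3))
  # uniform maps: every token equals the spatial mean
  alpha1 <- array(1, c(6, 5, 3))
  z <- token_learner_tokenize(x, alpha1)
  sm <- apply(x, 3, mean)
  for (i in 1:3) expect_equal(z[i, ], sm, tolerance = 1e-12)
  # one-hot map at (r, c): token is X[r, c, ] / (H * W)
  alpha2 <- array(0, c(6, 5, 1)); alpha2[4, 2, 1] <- 1
  z2 <- token_learner_tokenize(x, alpha2)
  expect_equal(as.vector(z2), x[4, 2, ] / 30, tolerance = 1e-12)
  # shape contract
  big <- array(runif(32 * 32 * 16), c(32, 32, 16))
  z3 <- token_learner_tokenize(big, array(runif(32 * 32 * 8), c(32, 32, 8)))
  expect_equal(dim(z3), c(8L, 16L))
  expect_error(token_learner_tokenize(x, array(1, c(6, 5, 0))), "at least one")
})

test_that("attention-map tokenizer: zeroed map convolutions give 0.5x pooled input", {
  cfg <- tokenmixer_config(latent_dim = 8L, depthwise_channels = 4L, num_tokens = 4L)
  x <- array(rnorm(6 * 6 * 8), c(6, 6, 8))
  w <- attention_map_tokenizer_weights(8, cfg, zero_maps = TRUE)
  z <- attention_map_tokenizer(x, cfg, w)
  expect_equal(dim(z), c(4L, 8L))
  pooled <- apply(x, 3, mean)
  for (i in 1:4) expect_equal(z[i, ], 0.5 * pooled, tolerance = 1e-12)
  # default config: exactly 4 tokens; fixed weights are deterministic
  wr <- attention_map_tokenizer_weights(8, cfg, seed = 2)
  z1 <- attention_map_tokenizer(x, cfg, wr)
  z2 <- attention_map_tokenizer(x, cfg, wr)
  expect_identical(z1, z2)
  expect_equal(nrow(z1), 4L)
})

test_that("ConvMixer stem follows the conv-GELU-BN order and stride arithmetic", {
  cfg <- convmixer_config(width = 8L, patch = 2L, depth = 1L, kernel = 3L)
  x <- tiny_image(16, 16, seed = 21)
  z <- convmixer_stem(x, cfg)
  expect_equal(dim(z), c(8L, 8L, 8L))
  wz <- convmixer_weights(cfg, zero = TRUE)
  expect_equal(convmixer_stem(x, cfg, wz), array(0, c(8, 8, 8)))
  # scalar oracle on a single patch
  xp <- tiny_image(2, 2, seed = 22)
  w <- convmixer_weights(cfg, seed = 23)
  z1 <- convmixer_stem(xp, cfg, w)
  expect_equal(dim(z1), c(1L, 1L, 8L))
  pre <- vapply(1:8, function(oc) sum(xp * w$stem_kernel[, , , oc]) + w$stem_bias[oc],
                numeric(1))
  act <- pre * pnorm(pre)
  expect_equal(as.vector(z1), act * w$stem_bn_gamma / sqrt(1 + 1e-5) + w$stem_bn_beta,
               tolerance = 1e-10)
  expect_error(convmixer_stem(tiny_image(15, 15, 1), cfg), "divide")
})

test_that("ConvMixer block preserves shape and matches the scalar oracle", {
  cfg <- convmixer_config(width = 4L, patch = 2L, depth = 1L, kernel = 3L)
  z <- array(rnorm(5 * 5 * 4), c(5, 5, 4))
  out <- convmixer_block(z, cfg)
  expect_equal(dim(out), dim(z))
  wz <- convmixer_weights(cfg, zero = TRUE)
  expect_equal(convmixer_block(array(0, c(5, 5, 4)), cfg, wz), array(0, c(5, 5, 4)))
  expect_error(convmixer_block(array(0, c(5, 5, 3)), cfg), "width")
  # 1x1 spatial input: depthwise reduces to its center tap
  w <- convmixer_weights(cfg, seed = 31)
  x1 <- array(rnorm(4), c(1, 1, 4))
  out1 <- convmixer_block(x1, cfg, w)
  gelu <- function(v) v * pnorm(v)
  ctr <- (cfg$kernel + 1) / 2
  zprime <- gelu(as.vector(x1) * w$dw_kernel[ctr, ctr, ] + w$dw_bias) + as.vector(x1)
  zprime <- zprime * w$bn1_gamma / sqrt(1 + 1e-5) + w$bn1_beta
  pw <- as.vector(zprime %*% w$pw_kernel[1, 1, , ]) + w$pw_bias
  expected <- gelu(pw) * w$bn2_gamma / sqrt(1 + 1e-5) + w$bn2_beta
  expect_equal(as.vector(out1), expected, tolerance = 1e-10)
})

test_that("builders reproduce the four reference parameter totals exactly", {
  expect_equal(count_trainable_parameters(build_convmixer()), 577282)
  tl <- build_tokenlearner_model()
  tm <- build_tokenmixer()
  expect_equal(count_trainable_parameters(tl), 1402169)
  expect_equal(count_trainable_parameters(tm), 1403961)
  expect_equal(count_trainable_parameters(tm) - count_trainable_parameters(tl), 1792)
  expect_equal(count_trainable_parameters(build_vit()), 36376521)
})

test_that("inventories decompose sensibly and closed forms agree with builders", {
  tl <- build_tokenlearner_model()
  inv <- parameter_inventory(tl)
  expect_equal(sum(inv$count), count_trainable_parameters(tl))
  expect_equal(inv$count[inv$layer == "patch_embed.kernel"], 588 * 128)
  hits <- search_architecture_configs()
  expect_equal(hits$convmixer$width, 256L)
  expect_equal(hits$convmixer$depth, 6L)
  expect_true(any(hits$tokenlearner$latent_dim == 128 & hits$tokenlearner$layers == 4 &
                    hits$tokenlearner$num_tokens == 4 & hits$tokenlearner$n_classes == 2))
  expect_true(any(hits$vit$latent_dim == 64 & hits$vit$key_dim == 64 &
                    hits$vit$mlp_hidden == 128 & hits$vit$n_classes == 2))
})

test_that("parameter counts respond monotonically to capacity", {
  small <- vit_config(latent_dim = 16L, head_units = c(32L, 16L))
  big <- vit_config(latent_dim = 32L, head_units = c(32L, 16L))
  expect_lt(count_trainable_parameters(build_vit(small)),
            count_trainable_parameters(build_vit(big)))
  c5 <- convmixer_config(width = 16L, depth = 5L)
  c6 <- convmixer_config(width = 16L, depth = 6L)
  c7 <- convmixer_config(width = 16L, depth = 7L)
  d1 <- count_trainable_parameters(build_convmixer(c6)) -
    count_trainable_parameters(build_convmixer(c5))
  d2 <- count_trainable_parameters(build_convmixer(c7)) -
    count_trainable_parameters(build_convmixer(c6))
  expect_equal(d1, d2) # one block's worth of parameters per extra depth
})

test_that("model forwards honor the logits shape contracts", {
  x <- make_toy_tensors(c(2, 56, 56, 3), seed = 8)
  cfg <- tokenmixer_config(image_size = 56L, latent_dim = 16L, layers = 2L,
                           heads = 2L, insert_after = 1L, n_classes = 1L)
  m <- build_tokenmixer(cfg)
  p <- model_predict(m, x)
  expect_equal(dim(p), c(2L, 1L)) # sigmoid binary head
  expect_true(all(p > 0 & p < 1))
  cfg8 <- tokenlearner_config(image_size = 56L, latent_dim = 16L, layers = 2L,
                              heads = 2L, insert_after = 1L, n_classes = 8L)
  m8 <- build_tokenlearner_model(cfg8)
  p8 <- model_predict(m8, x)
  expect_equal(dim(p8), c(2L, 8L))
  expect_equal(rowSums(p8), rep(1, 2), tolerance = 1e-9)
  cmx <- build_convmixer(convmixer_config(width = 8L, patch = 8L, depth = 1L,
                                          kernel = 3L, image_size = 56L))
  pc <- model_predict(cmx, x)
  expect_equal(dim(pc), c(2L, 2L))
  # architecture determinism: same config, same seed -> identical inventories
  expect_identical(parameter_inventory(build_tokenmixer(cfg)),
                   parameter_inventory(build_tokenmixer(cfg)))
})
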