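# Model configurations (frozen by the shipped constraint search, see
# search_architecture_configs()) and the four builders.

#' Compact vision transformer configuration
#'
#' Defaults are the frozen reference configuration: 224x224 input, 14x14
#' patches (256 tokens), 8 pre-norm encoder layers with 4 heads of per-head
#' dimension 64, latent dimension 64, encoder MLP (128, 64), flattened
#' representation into a (2048, 1024) head, 2-unit softmax output, and a
#' trainable input-standardization layer — 36,376,521 trainable parameters.
#'
#' @param image_size input side in pixels.
#' @param patch_size patch side in pixels.
#' @param layers number of encoder blocks.
#' @param heads attention heads per block.
#' @param latent_dim token dimension D.
#' @param key_dim per-head query/key/value dimension.
#' @param mlp_hidden hidden width of each block's MLP.
#' @param head_units widths of the classification head MLP.
#' @param n_classes output units (2-unit softmax for the binary task).
#' @param input_norm include the trainable input-standardization layer.
#' @return a `vit_config` list.
#' @export
vit_config <- function(image_size = 224L, patch_size = 14L, layers = 8L,
                       heads = 4L, latent_dim = 64L, key_dim = latent_dim,
                       mlp_hidden = 2L * latent_dim,
                       head_units = c(2048L, 1024L), n_classes = 2L,
                       input_norm = TRUE) {
  cfg <- list(image_size = as.integer(image_size), patch_size = as.integer(patch_size),
              layers = as.integer(layers), heads = as.integer(heads),
              latent_dim = as.integer(latent_dim), key_dim = as.integer(key_dim),
              mlp_hidden = as.integer(mlp_hidden), head_units = as.integer(head_units),
              n_classes = as.integer(n_classes), input_norm = isTRUE(input_norm))
  class(cfg) <- c("vit_config", "model_config")
  cfg
}

#' TokenLearner model configuration
#'
#' Defaults are the frozen reference configuration: conv patch embedding to
#' D = 128 (no positional embedding), 4 encoder layers with 4 heads of
#' per-head dimension 128 and MLP (256, 128), an adaptive tokenizer with 4
#' bias-free 3x3 map convolutions inserted after block 3 reducing 256 tokens
#' to 4, GAP head with 2-unit softmax — 1,402,169 trainable parameters.
#'
#' @inheritParams vit_config
#' @param num_tokens number of adaptive tokens S produced by the tokenizer.
#' @param map_kernel spatial kernel of the map-generating convolutions.
#' @param insert_after index of the encoder block after which the tokenizer
#'   is inserted.
#' @export
tokenlearner_config <- function(image_size = 224L, patch_size = 14L, layers = 4L,
                                heads = 4L, latent_dim = 128L, key_dim = latent_dim,
                                mlp_hidden = 2L * latent_dim, num_tokens = 4L,
                                map_kernel = 3L, insert_after = min(3L, layers),
                                n_classes = 2L, input_norm = TRUE) {
  cfg <- list(image_size = as.integer(image_size), patch_size = as.integer(patch_size),
              layers = as.integer(layers), heads = as.integer(heads),
              latent_dim = as.integer(latent_dim), key_dim = as.integer(key_dim),
              mlp_hidden = as.integer(mlp_hidden), num_tokens = as.integer(num_tokens),
              map_kernel = as.integer(map_kernel), insert_after = as.integer(insert_after),
              n_classes = as.integer(n_classes), input_norm = isTRUE(input_norm))
  if (cfg$insert_after < 1L || cfg$insert_after > cfg$layers) {
    stop("insert_after must lie in [1, layers]")
  }
  class(cfg) <- c("tokenlearner_config", "model_config")
  cfg
}

#' TokenMixer hybrid configuration
#'
#' The TokenLearner backbone whose tokenizer additionally applies a 5x5
#' depthwise convolution with batch normalization over a 64-channel subset of
#' the token grid (a partial depthwise mixing stage) before generating the
#' attention maps — 1,403,961 trainable parameters (+1,792 over
#' TokenLearner: 64 x (5*5 + 1) depthwise weights and 2 x 64 batch-norm
#' scale/shift).
#'
#' @inheritParams tokenlearner_config
#' @param depthwise_kernel spatial kernel of the depthwise mixing stage.
#' @param depthwise_channels number of leading channels the depthwise stage
#'   mixes (the remaining channels pass through untouched).
#' @export
tokenmixer_config <- function(image_size = 224L, patch_size = 14L, layers = 4L,
                              heads = 4L, latent_dim = 128L, key_dim = latent_dim,
                              mlp_hidden = 2L * latent_dim, num_tokens = 4L,
                              map_kernel = 3L, insert_after = min(3L, layers),
                              depthwise_kernel = 5L, depthwise_channels = min(64L, latent_dim),
                              n_classes = 2L, input_norm = TRUE) {
  cfg <- tokenlearner_config(image_size, patch_size, layers, heads, latent_dim,
                             key_dim, mlp_hidden, num_tokens, map_kernel,
                             insert_after, n_classes, input_norm)
  cfg$depthwise_kernel <- as.integer(depthwise_kernel)
  cfg$depthwise_channels <- as.integer(depthwise_channels)
  if (cfg$depthwise_channels > cfg$latent_dim) {
    stop("depthwise_channels cannot exceed latent_dim")
  }
  class(cfg) <- c("tokenmixer_config", "tokenlearner_config", "model_config")
  cfg
}

#' ConvMixer configuration
#'
#' Defaults are the frozen reference configuration: width h = 256, stem
#' patch p = 8, depth 6, depthwise kernel 9, 2-unit softmax head — 577,282
#' trainable parameters.
#'
#' @param width embedding width h (channels).
#' @param patch stem patch size p (kernel = stride = p).
#' @param depth number of mixer blocks.
#' @param kernel depthwise kernel side.
#' @param n_classes output units.
#' @param image_size input side in pixels.
#' @export
convmixer_config <- function(width = 256L, patch = 8L, depth = 6L, kernel = 9L,
                             n_classes = 2L, image_size = 224L) {
  cfg <- list(width = as.integer(width), patch = as.integer(patch),
              depth = as.integer(depth), kernel = as.integer(kernel),
              n_classes = as.integer(n_classes), image_size = as.integer(image_size))
  if (any(unlist(cfg) < 1L)) stop("all ConvMixer dimensions must be >= 1")
  class(cfg) <- c("convmixer_config", "model_config")
  cfg
}

new_model <- function(name, config, ps, forward, head_type, n_classes) {
  structure(list(name = name, config = config, ps = ps, forward = forward,
                 head_type = head_type, n_classes = n_classes),
            class = "tm_model")
}

#' @export
print.tm_model <- function(x, ...) {
  cat(sprintf("<%s> %s head, %d classes, %s trainable parameters\n",
              x$name, x$head_type, x$n_classes,
              format(count_trainable_parameters(x), big.mark = ",")))
  invisible(x)
}

head_type_for <- function(n_classes) if (n_classes == 1L) "sigmoid" else "softmax"

# shared classification head: (b, d) -> logits (b, n_classes)
make_head <- function(ps, d_in, head_units, n_classes) {
  fns <- list()
  d <- d_in
  for (i in seq_along(head_units)) {
    fns[[i]] <- layer_dense(ps, paste0("head.fc", i), d, head_units[i])
    d <- head_units[i]
  }
  out <- layer_dense(ps, "head.out", d, n_classes)
  function(x2) {
    for (f in fns) x2 <- ad_gelu(f(x2))
    out(x2)
  }
}

#' Build the compact vision transformer
#'
#' Patchify (14x14) -> linear patch embedding + learned positional embedding
#' -> pre-norm encoder blocks -> final layer norm -> flatten -> MLP head.
#'
#' @param config a [vit_config()].
#' @param seed integer seed for weight initialization.
#' @return a `tm_model` handle with attached parameter inventory.
#' @export
build_vit <- function(config = vit_config(), seed = 1L) {
  set.seed(seed)
  img <- config$image_size; P <- config$patch_size; D <- config$latent_dim
  N <- compute_num_patches(img, img, P)
  pdim <- P * P * 3L
  ps <- new_param_store()
  std <- if (config$input_norm) layer_input_standardize(ps) else NULL
  embed <- layer_dense(ps, "patch_embed", pdim, D)
  pos <- layer_pos_embedding(ps, "pos_embed", N, D)
  blocks <- lapply(seq_len(config$layers), function(i) {
    layer_encoder_block(ps, sprintf("encoder%d", i), D, config$heads,
                        config$key_dim, config$mlp_hidden)
  })
  final_ln <- layer_layernorm(ps, "final_ln", D)
  head <- make_head(ps, N * D, config$head_units, config$n_classes)
  pidx <- patch_index(img, img, 3L, P, grid = "col")
  pidx_v <- as.vector(t(pidx)) # token-major gather order
  forward <- function(x, training = FALSE) {
    b <- dim(ad_value(x))[1]
    x <- as_ad(x)
    if (!is.null(std)) x <- std(x)
    xm <- ad_reshape(x, c(b, img * img * 3L))
    patches <- ad_reshape(ad_index_cols(xm, pidx_v), c(b, N, pdim))
    tok <- ad_reshape(embed(ad_reshape(patches, c(b * N, pdim))), c(b, N, D))
    tok <- pos(tok)
    for (blk in blocks) tok <- blk(tok, b, N)
    flat <- ad_reshape(final_ln(ad_reshape(tok, c(b * N, D))), c(b, N * D))
    head(flat)
  }
  new_model("vit", config, ps, forward, head_type_for(config$n_classes), config$n_classes)
}

# shared token-transformer trunk for the TokenLearner / TokenMixer builders
build_token_model <- function(config, seed, hybrid) {
  set.seed(seed)
  img <- config$image_size; P <- config$patch_size; D <- config$latent_dim
  N <- compute_num_patches(img, img, P)
  gh <- img %/% P
  pdim <- P * P * 3L
  S <- config$num_tokens
  if (S <= 0) stop("num_tokens must be positive")
  ps <- new_param_store()
  std <- if (config$input_norm) layer_input_standardize(ps) else NULL
  embed <- layer_dense(ps, "patch_embed", pdim, D)
  pre_blocks <- lapply(seq_len(config$insert_after), function(i) {
    layer_encoder_block(ps, sprintf("encoder%d", i), D, config$heads,
                        config$key_dim, config$mlp_hidden)
  })
  tok_ln <- layer_layernorm(ps, "tokenizer.ln", D)
  if (hybrid) {
    dw <- layer_depthwise(ps, "tokenizer.depthwise", config$depthwise_kernel,
                          config$depthwise_channels, use_bias = TRUE)
    dw_bn <- layer_batchnorm(ps, "tokenizer.bn", config$depthwise_channels)
  }
  k <- config$map_kernel
  map1 <- layer_conv2d(ps, "tokenizer.map1", k, D, S, padding = "same", use_bias = FALSE)
  map2 <- layer_conv2d(ps, "tokenizer.map2", k, S, S, padding = "same", use_bias = FALSE)
  map3 <- layer_conv2d(ps, "tokenizer.map3", k, S, S, padding = "same", use_bias = FALSE)
  map4 <- layer_conv2d(ps, "tokenizer.map4", k, S, S, padding = "same", use_bias = FALSE)
  post_blocks <- lapply(seq.int(config$insert_after + 1L, length.out = config$layers - config$insert_after),
                        function(i) {
    layer_encoder_block(ps, sprintf("encoder%d", i), D, config$heads,
                        config$key_dim, config$mlp_hidden)
  })
  final_ln <- layer_layernorm(ps, "final_ln", D)
  out <- layer_dense(ps, "head.out", D, config$n_classes)
  pidx <- patch_index(img, img, 3L, P, grid = "col")
  pidx_v <- as.vector(t(pidx))
  forward <- function(x, training = FALSE) {
    b <- dim(ad_value(x))[1]
    x <- as_ad(x)
    if (!is.null(std)) x <- std(x)
    xm <- ad_reshape(x, c(b, img * img * 3L))
    patches <- ad_reshape(ad_index_cols(xm, pidx_v), c(b, N, pdim))
    tok <- ad_reshape(embed(ad_reshape(patches, c(b * N, pdim))), c(b, N, D))
    for (blk in pre_blocks) tok <- blk(tok, b, N)
    # adaptive tokenization on the spatial token grid
    grid <- ad_reshape(tok, c(b, gh, gh, D))
    normed <- ad_reshape(tok_ln(ad_reshape(grid, c(b * gh * gh, D))), c(b, gh, gh, D))
    if (hybrid) {
      dc <- config$depthwise_channels
      mixed <- dw_bn(dw(ad_slice_channels(normed, seq_len(dc))), training = training)
      normed <- if (dc < D) {
        ad_concat_channels(mixed, ad_slice_channels(normed, (dc + 1L):D))
      } else mixed
    }
    a <- ad_gelu(map1(normed))
    a <- ad_gelu(map2(a))
    a <- ad_gelu(map3(a))
    alpha <- ad_sigmoid(map4(a))
    tok <- ad_map_pool(grid, alpha) # (b, S, D)
    for (blk in post_blocks) tok <- blk(tok, b, S)
    rep2 <- final_ln(ad_reshape(tok, c(b * S, D)))
    pooled <- ad_mean_axis(ad_reshape(rep2, c(b, S, D)), 2L)
    out(pooled)
  }
  new_model(if (hybrid) "tokenmixer" else "tokenlearner", config, ps, forward,
            head_type_for(config$n_classes), config$n_classes)
}

#' Build the TokenLearner model
#'
#' Patch embedding as in the ViT, encoder blocks over the full 256-token
#' sequence, then the adaptive tokenizer reduces the sequence to `S` tokens
#' (S < N) processed by the remaining encoder blocks; GAP head.
#'
#' @param config a [tokenlearner_config()].
#' @param seed integer seed for weight initialization.
#' @export
build_tokenlearner_model <- function(config = tokenlearner_config(), seed = 1L) {
  build_token_model(config, seed, hybrid = FALSE)
}

#' Build the TokenMixer hybrid model
#'
#' The TokenLearner backbone whose tokenizer first mixes the token grid with
#' a partial depthwise convolution + batch normalization before generating
#' the spatial attention maps.
#'
#' @param config a [tokenmixer_config()].
#' @param seed integer seed for weight initialization.
#' @export
build_tokenmixer <- function(config = tokenmixer_config(), seed = 1L) {
  build_token_model(config, seed, hybrid = TRUE)
}

#' Build the ConvMixer model
#'
#' Stem (conv kernel = stride = p, GELU, BN) -> `depth` mixer blocks
#' (depthwise + residual + BN, pointwise + BN) -> global average pooling ->
#' fully connected classifier.
#'
#' @param config a [convmixer_config()].
#' @param n_classes output units (overrides the config).
#' @param seed integer seed for weight initialization.
#' @export
build_convmixer <- function(config = convmixer_config(), n_classes = config$n_classes,
                            seed = 1L) {
  set.seed(seed)
  h <- config$width; p <- config$patch; k <- config$kernel
  ps <- new_param_store()
  stem <- layer_conv2d(ps, "stem.conv", p, 3L, h, stride = p, padding = "valid")
  stem_bn <- layer_batchnorm(ps, "stem.bn", h)
  blocks <- lapply(seq_len(config$depth), function(i) {
    list(dw = layer_depthwise(ps, sprintf("block%d.depthwise", i), k, h),
         bn1 = layer_batchnorm(ps, sprintf("block%d.bn1", i), h),
         pw = layer_conv2d(ps, sprintf("block%d.pointwise", i), 1L, h, h),
         bn2 = layer_batchnorm(ps, sprintf("block%d.bn2", i), h))
  })
  out <- layer_dense(ps, "head.out", h, n_classes)
  forward <- function(x, training = FALSE) {
    x <- as_ad(x)
    z <- stem_bn(ad_gelu(stem(x)), training = training)
    for (blk in blocks) {
      zp <- blk$bn1(ad_add(ad_gelu(blk$dw(z)), z), training = training)
      z <- blk$bn2(ad_gelu(blk$pw(zp)), training = training)
    }
    out(ad_mean_axis(z, c(2L, 3L)))
  }
  new_model("convmixer", config, ps, forward, head_type_for(n_classes), n_classes)
}

#' Count the trainable parameters of a built model
#'
#' Sums the element counts of every trainable array in the model's inventory
#' (weights, biases, normalization scale/shift, positional embeddings, the
#' input-standardization layer). Batch-norm running statistics are state,
#' not parameters, and are excluded.
#'
#' @param model a `tm_model` handle.
#' @return integer total.
#' @export
count_trainable_parameters <- function(model) {
  sum(unlist(model$ps$inventory))
}

#' Per-layer trainable-parameter inventory
#'
#' @param model a `tm_model` handle.
#' @return data.frame with columns `layer` and `count`, in construction order.
#' @export
parameter_inventory <- function(model) {
  data.frame(layer = names(model$ps$inventory),
             count = unname(unlist(model$ps$inventory)),
             stringsAsFactors = FALSE)
}

#' Forward inference: class probabilities
#'
#' Runs the model in inference mode over minibatches and returns class
#' probabilities: a single column under a sigmoid head, one column per class
#' under a softmax head.
#'
#' @param model a `tm_model`.
#' @param x `(n, H, W, 3)` image batch.
#' @param batch_size minibatch size used during inference.
#' @return `(n, n_classes)` probability matrix.
#' @export
model_predict <- function(model, x, batch_size = 32L) {
  n <- dim(x)[1]
  outs <- vector("list", ceiling(n / batch_size))
  for (i in seq_along(outs)) {
    rows <- ((i - 1L) * batch_size + 1L):min(i * batch_size, n)
    logits <- ad_value(model$forward(x[rows, , , , drop = FALSE], training = FALSE))
    outs[[i]] <- if (model$head_type == "sigmoid") {
      1 / (1 + exp(-logits))
    } else {
      e <- exp(logits - apply(logits, 1L, max))
      e / rowSums(e)
    }
  }
  do.call(rbind, outs)
}
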