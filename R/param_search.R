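# The architecture hyperparameters that the reference totals do not print
# (latent dims, MLP widths, token counts, the ConvMixer geometry) are fixed
# by an exhaustive integer search over candidate configurations whose
# closed-form parameter counts must reproduce the published totals exactly.
# This module ships that search; the winning configurations are frozen as
# the config constructors' defaults.

count_encoder_layer <- function(d, heads, key_dim, mlp_hidden) {
  hk <- heads * key_dim
  mha <- 3 * (d * hk + hk) + (hk * d + d)
  2 * (2 * d) + mha + (d * mlp_hidden + mlp_hidden) + (mlp_hidden * d + d)
}

count_vit <- function(d, layers, heads, key_dim, mlp_hidden, head_units,
                      n_classes, n_patches = 256L, patch_dim = 588L,
                      input_norm = TRUE) {
  total <- if (input_norm) 7 else 0
  total <- total + patch_dim * d + d + n_patches * d
  total <- total + layers * count_encoder_layer(d, heads, key_dim, mlp_hidden)
  total <- total + 2 * d
  din <- n_patches * d
  for (h in head_units) { total <- total + din * h + h; din <- h }
  total + din * n_classes + n_classes
}

count_token_model <- function(d, layers, heads, key_dim, mlp_hidden, num_tokens,
                              map_kernel, n_classes, hybrid = FALSE,
                              depthwise_kernel = 5L, depthwise_channels = 64L,
                              patch_dim = 588L, input_norm = TRUE) {
  S <- num_tokens; k <- map_kernel
  total <- if (input_norm) 7 else 0
  total <- total + patch_dim * d + d
  total <- total + layers * count_encoder_layer(d, heads, key_dim, mlp_hidden)
  total <- total + 2 * d # tokenizer layer norm
  if (hybrid) {
    total <- total + depthwise_kernel^2 * depthwise_channels + depthwise_channels +
      2 * depthwise_channels
  }
  total <- total + k^2 * d * S + 3 * (k^2 * S * S) # bias-free map convolutions
  total <- total + 2 * d # final layer norm
  total + d * n_classes + n_classes
}

count_convmixer <- function(width, patch, depth, kernel, n_classes) {
  h <- width
  stem <- 3 * patch^2 * h + h + 2 * h
  blk <- (kernel^2 * h + h + 2 * h) + (h * h + h + 2 * h)
  stem + depth * blk + h * n_classes + n_classes
}

#' Search architecture configurations matching the reference totals
#'
#' Enumerates candidate hyperparameter grids for each family and returns the
#' configurations whose closed-form trainable-parameter counts equal the
#' four reference totals exactly. The shipped config constructor defaults
#' are the winners of this search; the builders' inventories are tested to
#' agree with the closed forms.
#'
#' @param targets named totals to match.
#' @return list of data.frames of exact hits per family.
#' @export
search_architecture_configs <- function(targets = c(vit = 36376521, convmixer = 577282,
                                                    tokenlearner = 1402169,
                                                    tokenmixer = 1403961)) {
  vit_hits <- list()
  for (d in c(32L, 48L, 64L, 96L, 128L)) {
    for (key_dim in unique(c(d %/% 4L, d))) {
      for (mlp_hidden in c(d, 2L * d, 4L * d)) {
        for (n_classes in 1:2) {
          tot <- count_vit(d, 8L, 4L, key_dim, mlp_hidden, c(2048L, 1024L), n_classes)
          if (tot == targets[["vit"]]) {
            vit_hits[[length(vit_hits) + 1L]] <-
              data.frame(latent_dim = d, key_dim = key_dim, mlp_hidden = mlp_hidden,
                         n_classes = n_classes)
          }
        }
      }
    }
  }
  cm_hits <- list()
  for (width in seq(32L, 512L, by = 8L)) {
    for (patch in 1:14) {
      for (kernel in c(3L, 5L, 7L, 9L, 11L)) {
        for (depth in 1:16) {
          for (n_classes in 1:2) {
            if (count_convmixer(width, patch, depth, kernel, n_classes) ==
                targets[["convmixer"]]) {
              cm_hits[[length(cm_hits) + 1L]] <-
                data.frame(width = width, patch = patch, depth = depth,
                           kernel = kernel, n_classes = n_classes)
            }
          }
        }
      }
    }
  }
  tl_hits <- list()
  for (d in c(64L, 96L, 128L, 192L, 256L)) {
    for (key_dim in unique(c(d %/% 4L, d))) {
      for (mlp_hidden in c(d, 2L * d, 4L * d)) {
        for (layers in 1:8) {
          for (S in c(1L, 2L, 4L, 8L)) {
            for (n_classes in 1:2) {
              tl <- count_token_model(d, layers, 4L, key_dim, mlp_hidden, S, 3L, n_classes)
              tm <- count_token_model(d, layers, 4L, key_dim, mlp_hidden, S, 3L, n_classes,
                                      hybrid = TRUE)
              if (tl == targets[["tokenlearner"]] && tm == targets[["tokenmixer"]]) {
                tl_hits[[length(tl_hits) + 1L]] <-
                  data.frame(latent_dim = d, key_dim = key_dim, mlp_hidden = mlp_hidden,
                             layers = layers, num_tokens = S, n_classes = n_classes)
              }
            }
          }
        }
      }
    }
  }
  list(vit = do.call(rbind, vit_hits),
       convmixer = do.call(rbind, cm_hits),
       tokenlearner = do.call(rbind, tl_hits))
}
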