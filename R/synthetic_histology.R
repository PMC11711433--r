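# Seeded generator of class-separable synthetic histology-like images in the
# BreakHis directory layout, so the full pipeline is testable without the
# external archive.

# Per-(subtype x magnification) image counts of the reference archive,
# scaled down by 10 (rounded up); preserves the benign:malignant imbalance
# direction. Rows: subtypes; columns: 40x, 100x, 200x, 400x.
reference_counts <- function() {
  full <- rbind(
    AD = c(114, 113, 111, 106),
    FI = c(253, 260, 264, 253),
    PH = c(109, 121, 108, 115),
    TU = c(149, 150, 140, 130),
    DU = c(864, 903, 896, 788),
    LO = c(156, 170, 163, 137),
    MU = c(205, 222, 196, 169),
    PA = c(145, 142, 135, 138)
  )
  colnames(full) <- c("40", "100", "200", "400")
  full
}

default_subtype_params <- function() {
  # pairwise-distinct base hues (RGB in [0,1]), blob densities per 1e4 px^2,
  # blob radius mean/sd (px, at 40x), background noise sd
  data.frame(
    subtype = SUBTYPES,
    r = c(0.85, 0.75, 0.90, 0.65, 0.55, 0.45, 0.70, 0.35),
    g = c(0.55, 0.75, 0.35, 0.60, 0.30, 0.50, 0.20, 0.30),
    b = c(0.75, 0.85, 0.60, 0.80, 0.55, 0.75, 0.45, 0.60),
    blob_density = c(1.0, 0.6, 1.4, 0.8, 2.2, 1.6, 1.2, 1.9),
    blob_radius_mean = c(6, 9, 5, 8, 4, 6, 7, 5),
    blob_radius_sd = c(1.5, 2, 1.2, 2, 1, 1.5, 1.8, 1.2),
    noise_sd = c(0.04, 0.04, 0.05, 0.04, 0.05, 0.05, 0.04, 0.05),
    stringsAsFactors = FALSE
  )
}

#' Synthetic dataset specification
#'
#' @param subtypes data.frame of per-subtype texture parameters (columns
#'   `subtype`, `r`, `g`, `b` base hue, `blob_density` per 1e4 px^2,
#'   `blob_radius_mean`, `blob_radius_sd` in px, `noise_sd`); defaults to
#'   eight pairwise-distinct parameter sets.
#' @param counts matrix of image counts, rows = subtypes, columns =
#'   magnifications ("40", "100", "200", "400"); defaults to the reference
#'   archive counts scaled down by 10 (rounded up).
#' @param image_size `(height, width)` before any resize; the default
#'   460 x 700 exercises the resize path with a realistic aspect ratio.
#' @param seed integer seed; the full dataset is a pure function of
#'   `(spec, seed)`.
#' @return a `synthetic_spec` list.
#' @export
synthetic_spec <- function(subtypes = default_subtype_params(),
                           counts = ceiling(reference_counts() / 10),
                           image_size = c(460L, 700L), seed = 20L) {
  stopifnot(all(counts >= 0), all(subtypes$blob_density >= 0),
            all(subtypes$noise_sd >= 0))
  hues <- as.matrix(subtypes[, c("r", "g", "b")])
  if (anyDuplicated(hues) > 0) stop("per-subtype hue triplets must be pairwise distinct")
  if (any(hues < 0 | hues > 1)) stop("hues must lie in [0, 1]")
  structure(list(subtypes = subtypes, counts = counts,
                 image_size = as.integer(image_size), seed = as.integer(seed)),
            class = "synthetic_spec")
}

# Render one synthetic frame: background Gaussian texture around the base
# hue plus Poisson-many elliptical nuclei blobs; magnification scales blob
# radii and adds blur at low magnification.
render_synthetic_image <- function(pars, magnification, image_size, rng) {
  h <- image_size[1]; w <- image_size[2]
  base <- c(pars$r, pars$g, pars$b)
  img <- array(rep(base, each = h * w), c(h, w, 3)) +
    array(rng$rnorm(h * w * 3, sd = pars$noise_sd), c(h, w, 3))
  scale <- magnification / 40
  n_blobs <- rng$rpois(1L, pars$blob_density * h * w / 1e4 / scale)
  if (n_blobs > 0) {
    cy <- rng$runif(n_blobs, 1, h)
    cx <- rng$runif(n_blobs, 1, w)
    rad <- pmax(1.5, rng$rnorm(n_blobs, pars$blob_radius_mean * scale,
                               pars$blob_radius_sd * scale))
    asp <- rng$runif(n_blobs, 0.6, 1.4)
    theta <- rng$runif(n_blobs, 0, pi)
    shade <- rng$runif(n_blobs, 0.35, 0.65)
    for (i in seq_len(n_blobs)) {
      r <- rad[i]
      half <- ceiling(r * max(1, asp[i])) + 1L
      ys <- max(1, floor(cy[i] - half)):min(h, ceiling(cy[i] + half))
      xs <- max(1, floor(cx[i] - half)):min(w, ceiling(cx[i] + half))
      if (length(ys) == 0 || length(xs) == 0) next
      dy <- matrix(ys - cy[i], length(ys), length(xs))
      dx <- matrix(xs - cx[i], length(ys), length(xs), byrow = TRUE)
      u <- dy * cos(theta[i]) + dx * sin(theta[i])
      v <- -dy * sin(theta[i]) + dx * cos(theta[i])
      m2 <- (u / r)^2 + (v / (r * asp[i]))^2
      mask <- pmax(0, 1 - m2) # soft elliptical falloff
      for (ch in 1:3) {
        plane <- img[ys, xs, ch]
        img[ys, xs, ch] <- plane * (1 - mask) + mask * base[ch] * shade[i]
      }
    }
  }
  if (magnification <= 100) {
    sigma <- if (magnification == 40) 1.5 else 0.8
    img <- aperm(EBImage::imageData(EBImage::gblur(
      EBImage::Image(aperm(img, c(2, 1, 3)), colormode = "Color"), sigma = sigma)),
      c(2, 1, 3))
  }
  pmin(pmax(img, 0), 1)
}

#' Generate a synthetic dataset in BreakHis layout
#'
#' Writes the specified counts of PNG images into
#' `<out_dir>/<magnification>/<subtype>/` and a manifest CSV. Byte-identical
#' output for identical `(spec, seed)`.
#'
#' @param spec a [synthetic_spec()].
#' @param out_dir output directory (created if missing).
#' @return the manifest path (CSV with columns `path,magnification,subtype`),
#'   invisibly the records data.frame as attribute `"records"`.
#' @export
generate_dataset <- function(spec = synthetic_spec(), out_dir) {
  if (sum(spec$counts) == 0) stop("spec contains no images to generate")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  rows <- list()
  idx <- 0L
  for (mag in colnames(spec$counts)) {
    for (st in rownames(spec$counts)) {
      n <- spec$counts[st, mag]
      if (n == 0) next
      d <- file.path(out_dir, mag, st)
      dir.create(d, recursive = TRUE, showWarnings = FALSE)
      pars <- spec$subtypes[spec$subtypes$subtype == st, ]
      if (nrow(pars) != 1) stop("no texture parameters for subtype ", st)
      for (i in seq_len(n)) {
        idx <- idx + 1L
        rng <- seed_rng(derive_seed(spec$seed, idx))
        img <- render_synthetic_image(pars, as.integer(mag), spec$image_size, rng)
        f <- file.path(d, sprintf("%s_%s_%03d.png", st, mag, i))
        png::writePNG(img, f)
        rows[[idx]] <- data.frame(path = f, magnification = as.integer(mag),
                                  subtype = st, stringsAsFactors = FALSE)
      }
    }
  }
  man <- do.call(rbind, rows)
  manifest <- file.path(out_dir, "manifest.csv")
  out <- man
  out$path <- substring(out$path, nchar(out_dir) + 2L)
  utils::write.csv(out, manifest, row.names = FALSE, quote = FALSE)
  structure(manifest, records = new_records(man$path, man$magnification, man$subtype))
}

#' Seeded uniform test tensors
#'
#' @param shape integer vector `(n, h, w, c)`, all dims >= 1.
#' @param seed integer seed.
#' @return array of i.i.d. uniform `[0, 1]` values.
#' @export
make_toy_tensors <- function(shape, seed = 1L) {
  if (any(shape < 1)) stop("all dims must be >= 1")
  rng <- seed_rng(seed)
  array(rng$runif(prod(shape)), shape)
}
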