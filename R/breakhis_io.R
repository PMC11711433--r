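# Reading, splitting, resizing and augmenting magnification-stratified
# histopathology image collections laid out BreakHis-style:
#   root/<magnification>/<subtype>/*.png  (or a manifest CSV).

BENIGN_SUBTYPES <- c("AD", "FI", "PH", "TU")
MALIGNANT_SUBTYPES <- c("DU", "LO", "MU", "PA")
SUBTYPES <- c(BENIGN_SUBTYPES, MALIGNANT_SUBTYPES)
MAGNIFICATIONS <- c(40L, 100L, 200L, 400L)

#' Map a tumor subtype code to its binary class
#'
#' Adenosis-type benign subtypes (AD, FI, PH, TU) map to `benign`; the
#' carcinoma subtypes (DU, LO, MU, PA) map to `malignant`.
#'
#' @param subtype character vector of subtype codes.
#' @return character vector, `"benign"` or `"malignant"`.
#' @export
subtype_to_binary <- function(subtype) {
  bad <- setdiff(unique(subtype), SUBTYPES)
  if (length(bad) > 0) {
    stop("unknown subtype code(s): ", paste(bad, collapse = ", "))
  }
  ifelse(subtype %in% BENIGN_SUBTYPES, "benign", "malignant")
}

new_records <- function(path, magnification, subtype) {
  magnification <- as.integer(magnification)
  bad <- setdiff(unique(magnification), MAGNIFICATIONS)
  if (length(bad) > 0) stop("unknown magnification(s): ", paste(bad, collapse = ", "))
  data.frame(path = path,
             magnification = magnification,
             subtype = subtype,
             label_binary = subtype_to_binary(subtype),
             stringsAsFactors = FALSE)
}

#' Load image records from a directory tree or manifest CSV
#'
#' @param root_or_manifest either a directory laid out as
#'   `root/<magnification>/<subtype>/*.png|jpg`, or a CSV with columns
#'   `path,magnification,subtype`.
#' @param layout `"directory"` or `"manifest"`.
#' @return data.frame of records with columns `path`, `magnification`,
#'   `subtype`, `label_binary` (one row per image; pixels are loaded lazily
#'   by [load_pixels()]).
#' @export
load_records <- function(root_or_manifest, layout = c("directory", "manifest")) {
  layout <- match.arg(layout)
  if (layout == "manifest") {
    man <- utils::read.csv(root_or_manifest, stringsAsFactors = FALSE)
    need <- c("path", "magnification", "subtype")
    if (!all(need %in% names(man))) {
      stop("manifest must have columns ", paste(need, collapse = ","))
    }
    # relative paths resolve against the manifest's directory
    rel <- !grepl("^(/|[A-Za-z]:)", man$path)
    man$path[rel] <- file.path(dirname(root_or_manifest), man$path[rel])
    bad <- setdiff(unique(man$subtype), SUBTYPES)
    if (length(bad) > 0) {
      off <- man$path[man$subtype %in% bad][1]
      stop("unknown subtype code(s) ", paste(bad, collapse = ", "),
           " (e.g. for ", off, ")")
    }
    return(new_records(man$path, man$magnification, man$subtype))
  }
  files <- list.files(root_or_manifest, pattern = "\\.(png|jpg|jpeg)$",
                      recursive = TRUE, full.names = TRUE, ignore.case = TRUE)
  if (length(files) == 0) stop("no images found under ", root_or_manifest)
  parts <- strsplit(substring(files, nchar(root_or_manifest) + 2L), "/")
  ok <- vapply(parts, length, integer(1)) >= 3L
  if (!all(ok)) stop("unexpected layout for ", files[!ok][1],
                     " (want <magnification>/<subtype>/<file>)")
  mag <- vapply(parts, function(p) p[length(p) - 2L], character(1))
  sub <- vapply(parts, function(p) p[length(p) - 1L], character(1))
  bad <- setdiff(unique(sub), SUBTYPES)
  if (length(bad) > 0) {
    off <- files[sub %in% bad][1]
    stop("unknown subtype code(s) ", paste(bad, collapse = ", "),
         " (e.g. for ", off, ")")
  }
  new_records(files, as.integer(mag), sub)
}

#' Stratified train/validation/test split
#'
#' First 20% of each class is sliced off as the test set, then 20% of the
#' remaining 80% as validation: 64/16/20 of the total, stratified by the
#' active label. Within each class, records are shuffled by the seed; the
#' test and validation shares are floored, remainders go to training.
#'
#' @param records record data.frame (see [load_records()]).
#' @param seed integer seed; identical seeds give identical partitions.
#' @param label column used for stratification: `"label_binary"` or
#'   `"subtype"`.
#' @return a `dataset_split`: list with `train`, `validation`, `test`
#'   record data.frames, plus `seed` and `ratios`.
#' @export
stratified_split <- function(records, seed = 1L, label = c("label_binary", "subtype")) {
  label <- match.arg(label)
  classes <- split(seq_len(nrow(records)), records[[label]])
  small <- names(classes)[vapply(classes, length, integer(1)) < 3L]
  if (length(small) > 0 || length(classes) < 2L) {
    stop("stratification impossible: class(es) with too few records: ",
         paste(if (length(small)) small else names(classes), collapse = ", "))
  }
  idx_test <- integer(0); idx_val <- integer(0); idx_train <- integer(0)
  rng <- seed_rng(seed)
  for (cl in sort(names(classes))) {
    ids <- classes[[cl]]
    ids <- ids[rng$sample_int(length(ids))]
    n <- length(ids)
    n_test <- floor(0.2 * n)
    n_val <- floor(0.2 * (n - n_test))
    idx_test <- c(idx_test, ids[seq_len(n_test)])
    idx_val <- c(idx_val, ids[n_test + seq_len(n_val)])
    idx_train <- c(idx_train, ids[-seq_len(n_test + n_val)])
  }
  structure(list(train = records[sort(idx_train), , drop = FALSE],
                 validation = records[sort(idx_val), , drop = FALSE],
                 test = records[sort(idx_test), , drop = FALSE],
                 seed = as.integer(seed),
                 ratios = c(train = 0.64, validation = 0.16, test = 0.20)),
            class = "dataset_split")
}

#' Write a split back to a manifest CSV with a `split` column
#'
#' @param split a `dataset_split`.
#' @param path output CSV path.
#' @return the path, invisibly.
#' @export
write_split_manifest <- function(split, path) {
  parts <- c("train", "val", "test")
  dfs <- Map(function(df, nm) { df$split <- nm; df },
             list(split$train, split$validation, split$test), parts)
  utils::write.csv(do.call(rbind, dfs), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# Bilinear sampler with nearest-edge (clamp) fill. rows/cols are matrices of
# fractional source coordinates (1-based) at which to sample each channel.
bilinear_sample <- function(img, rows, cols) {
  d <- dim(img)
  r0 <- pmin(pmax(floor(rows), 1), d[1]); r1 <- pmin(r0 + 1, d[1])
  c0 <- pmin(pmax(floor(cols), 1), d[2]); c1 <- pmin(c0 + 1, d[2])
  fr <- pmin(pmax(rows - r0, 0), 1); fc <- pmin(pmax(cols - c0, 0), 1)
  out <- array(0, c(dim(rows), d[3]))
  for (ch in seq_len(d[3])) {
    plane <- img[, , ch]
    v00 <- plane[cbind(as.vector(r0), as.vector(c0))]
    v01 <- plane[cbind(as.vector(r0), as.vector(c1))]
    v10 <- plane[cbind(as.vector(r1), as.vector(c0))]
    v11 <- plane[cbind(as.vector(r1), as.vector(c1))]
    v <- v00 * (1 - fr) * (1 - fc) + v01 * (1 - fr) * fc +
      v10 * fr * (1 - fc) + v11 * fr * fc
    out[, , ch] <- v
  }
  out
}

#' Bilinear resize to the model input resolution
#'
#' @param image `(h, w, 3)` array with values in `[0, 1]`.
#' @param size target side length (default 224).
#' @return `(size, size, 3)` array; the value range is preserved.
#' @export
resize_to_input <- function(image, size = 224L) {
  d <- dim(image)
  if (length(d) != 3L || d[3] != 3L) stop("input must be (h, w, 3)")
  if (d[1] == size && d[2] == size) return(image)
  # sample at pixel centers of the target grid mapped into the source grid
  rows <- ((seq_len(size) - 0.5) * d[1] / size) + 0.5
  cols <- ((seq_len(size) - 0.5) * d[2] / size) + 0.5
  bilinear_sample(image, matrix(rows, size, size), matrix(cols, size, size, byrow = TRUE))
}

#' Augmentation configuration
#'
#' Defaults: rotation range 5 degrees, width/height shift fractions 0.1,
#' zoom range 0.001, nearest-edge fill.
#'
#' @param rotation_range_deg maximal absolute rotation in degrees.
#' @param width_shift_frac,height_shift_frac maximal absolute shift as a
#'   fraction of width/height.
#' @param zoom_range maximal absolute relative zoom.
#' @param fill_mode `"nearest"` (edge replication), `"constant"` (zeros) or
#'   `"reflect"`.
#' @return an `augmentation_config` list.
#' @export
augmentation_config <- function(rotation_range_deg = 5, width_shift_frac = 0.1,
                                height_shift_frac = 0.1, zoom_range = 0.001,
                                fill_mode = c("nearest", "reflect", "constant")) {
  fill_mode <- match.arg(fill_mode)
  vals <- c(rotation_range_deg, width_shift_frac, height_shift_frac, zoom_range)
  if (any(vals < 0)) stop("augmentation ranges must be >= 0")
  structure(list(rotation_range_deg = rotation_range_deg,
                 width_shift_frac = width_shift_frac,
                 height_shift_frac = height_shift_frac,
                 zoom_range = zoom_range, fill_mode = fill_mode),
            class = "augmentation_config")
}

# Draw one set of augmentation parameters from a counting rng.
draw_augment_params <- function(config, rng) {
  u <- rng$runif(4L)
  list(angle = (2 * u[1] - 1) * config$rotation_range_deg * pi / 180,
       dx = (2 * u[2] - 1) * config$width_shift_frac,
       dy = (2 * u[3] - 1) * config$height_shift_frac,
       zoom = 1 + (2 * u[4] - 1) * config$zoom_range)
}

#' Random geometric augmentation of one image
#'
#' Applies a random rotation, width/height shift and zoom about the image
#' center, sampled uniformly within the configured ranges. Inverse-mapped
#' bilinear resampling; out-of-image coordinates follow the fill mode.
#' Deterministic given the generator state; shape and `[0, 1]` range are
#' preserved (with nearest fill).
#'
#' @param image `(h, w, 3)` array.
#' @param config an [augmentation_config()].
#' @param rng a counting generator from [seed_rng()].
#' @return augmented `(h, w, 3)` array.
#' @export
augment <- function(image, config = augmentation_config(), rng = seed_rng(1L)) {
  d <- dim(image)
  if (length(d) != 3L) stop("image must be (h, w, 3)")
  pars <- draw_augment_params(config, rng)
  if (pars$angle == 0 && pars$dx == 0 && pars$dy == 0 && pars$zoom == 1) {
    return(image)
  }
  h <- d[1]; w <- d[2]
  cy <- (h + 1) / 2; cx <- (w + 1) / 2
  gy <- matrix(seq_len(h), h, w) - cy
  gx <- matrix(seq_len(w), h, w, byrow = TRUE) - cx
  # inverse transform: rotate by -angle, unzoom, unshift
  ca <- cos(-pars$angle); sa <- sin(-pars$angle)
  sy <- (gy * ca - gx * sa) / pars$zoom + cy - pars$dy * h
  sx <- (gy * sa + gx * ca) / pars$zoom + cx - pars$dx * w
  if (config$fill_mode == "reflect") {
    refl <- function(v, n) {
      v <- (v - 1) %% (2 * n - 2)
      ifelse(v >= n - 1, 2 * n - 2 - v, v) + 1
    }
    sy <- refl(sy, h); sx <- refl(sx, w)
  }
  out <- bilinear_sample(image, sy, sx)
  if (config$fill_mode == "constant") {
    mask <- sy < 1 | sy > h | sx < 1 | sx > w
    for (ch in seq_len(d[3])) {
      plane <- out[, , ch]; plane[mask] <- 0; out[, , ch] <- plane
    }
  }
  out
}

#' Load and resize the pixels for a set of records
#'
#' Reads each image (PNG/JPEG, via EBImage), converts to `[0, 1]` RGB and
#' resizes to the model input resolution.
#'
#' @param records record data.frame.
#' @param size target side (default 224).
#' @return `(n, size, size, 3)` array.
#' @export
load_pixels <- function(records, size = 224L) {
  n <- nrow(records)
  out <- array(0, c(n, size, size, 3))
  for (i in seq_len(n)) {
    img <- load_image(records$path[i])
    out[i, , , ] <- resize_to_input(img, size)
  }
  out
}

# Read one image file as an (h, w, 3) array in [0, 1].
load_image <- function(path) {
  img <- EBImage::readImage(path)
  a <- EBImage::imageData(img)
  # EBImage stores (x, y, c); convert to (row, col, c)
  if (length(dim(a)) == 2L) a <- array(rep(a, 3), c(dim(a), 3))
  a <- aperm(a[, , 1:3, drop = FALSE], c(2, 1, 3))
  pmin(pmax(a, 0), 1)
}
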