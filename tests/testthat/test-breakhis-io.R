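# Directory/manifest loading, stratified splitting, resizing, augmentation.

write_tiny_png <- function(path, seed = 1) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  set.seed(seed)
  png::writePNG(array(runif(8 * 8 * 3), c(8, 8, 3)), path)
  path
}

make_tree <- function(root, spec) {
  # spec: data.frame(mag, subtype, n)
  for (i in seq_len(nrow(spec))) {
    for (j in seq_len(spec$n[i])) {
      write_tiny_png(file.path(root, spec$mag[i], spec$subtype[i],
                               sprintf("img%02d.png", j)), seed = i * 100 + j)
    }
  }
  root
}

test_that("directory trees load with labels derived from the layout", {
  root <- make_tree(withr::local_tempdir(),
                    data.frame(mag = "40", subtype = "FI", n = 3))
  recs <- load_records(root, "directory")
  expect_equal(nrow(recs), 3L)
  expect_true(all(recs$magnification == 40L))
  expect_true(all(recs$subtype == "FI"))
  expect_true(all(recs$label_binary == "benign"))
  expect_error(load_records(withr::local_tempdir(), "directory"), "no images")
  bad <- make_tree(withr::local_tempdir(),
                   data.frame(mag = "40", subtype = "XX", n = 1))
  expect_error(load_records(bad, "directory"), "XX")
})

test_that("manifests load and the subtype-to-binary map is total", {
  d <- withr::local_tempdir()
  write_tiny_png(file.path(d, "p.png"))
  man <- file.path(d, "manifest.csv")
  writeLines(c("path,magnification,subtype", "p.png,200,DU"), man)
  recs <- load_records(man, "manifest")
  expect_equal(recs$label_binary, "malignant")
  writeLines(c("path,magnification,subtype", "p.png,200,XX"), man)
  expect_error(load_records(man, "manifest"), "XX")
  expect_equal(subtype_to_binary(c("AD", "FI", "PH", "TU")), rep("benign", 4))
  expect_equal(subtype_to_binary(c("DU", "LO", "MU", "PA")), rep("malignant", 4))
  expect_error(subtype_to_binary("QQ"), "QQ")
})

fake_records <- function(n_per_class) {
  subs <- c(rep("FI", n_per_class[1]), rep("DU", n_per_class[2]))
  new_recs <- data.frame(path = sprintf("img%03d.png", seq_along(subs)),
                         magnification = 40L, subtype = subs,
                         stringsAsFactors = FALSE)
  new_recs$label_binary <- subtype_to_binary(new_recs$subtype)
  new_recs
}

test_that("stratified split produces exact 64/16/20 partitions", {
  recs <- fake_records(c(50, 50))
  sp <- stratified_split(recs, seed = 7)
  expect_equal(nrow(sp$train), 64L)
  expect_equal(nrow(sp$validation), 16L)
  expect_equal(nrow(sp$test), 20L)
  for (part in list(sp$train, sp$validation, sp$test)) {
    tab <- table(part$label_binary)
    expect_equal(unname(tab["benign"]), unname(tab["malignant"]))
  }
  expect_equal(sum(table(sp$train$label_binary)), 64L)
  # partition: disjoint and complete
  all_paths <- c(sp$train$path, sp$validation$path, sp$test$path)
  expect_equal(sort(all_paths), sort(recs$path))
  expect_equal(anyDuplicated(all_paths), 0L)
})

test_that("splitting is deterministic in the seed and errors on tiny classes", {
  recs <- fake_records(c(20, 30))
  a <- stratified_split(recs, seed = 3)
  b <- stratified_split(recs, seed = 3)
  expect_identical(a$train$path, b$train$path)
  expect_identical(a$test$path, b$test$path)
  c_ <- stratified_split(recs, seed = 4)
  expect_false(identical(a$train$path, c_$train$path))
  solo <- fake_records(c(5, 0))
  expect_error(stratified_split(solo, 1), "stratification impossible")
})

test_that("split stratification error stays within one record per class", {
  recs <- fake_records(c(33, 67))
  sp <- stratified_split(recs, seed = 2)
  n_tot <- nrow(recs)
  for (part in list(sp$train, sp$validation, sp$test)) {
    for (cl in c("benign", "malignant")) {
      frac_part <- sum(part$label_binary == cl) / nrow(part)
      frac_tot <- sum(recs$label_binary == cl) / n_tot
      expect_lte(abs(frac_part - frac_tot), 1 / nrow(part) + 1e-12)
    }
  }
  man <- file.path(withr::local_tempdir(), "split.csv")
  write_split_manifest(sp, man)
  out <- read.csv(man)
  expect_equal(sort(unique(out$split)), c("test", "train", "val"))
  expect_equal(nrow(out), n_tot)
})

test_that("resize honors the shape contract and preserves values", {
  img <- tiny_image(700, 460, seed = 6)
  out <- resize_to_input(img)
  expect_equal(dim(out), c(224L, 224L, 3L))
  expect_true(all(out >= 0 & out <= 1))
  same <- tiny_image(224, 224, seed = 7)
  expect_identical(resize_to_input(same), same)
  const <- array(0.42, c(50, 80, 3))
  expect_equal(resize_to_input(const), array(0.42, c(224, 224, 3)), tolerance = 1e-12)
  expect_error(resize_to_input(array(0, c(10, 10, 1))), "3")
})

test_that("augmentation honors identity, determinism and range contracts", {
  img <- tiny_image(224, 224, seed = 8)
  zero <- augmentation_config(0, 0, 0, 0, fill_mode = "nearest")
  expect_identical(augment(img, zero, seed_rng(1)), img)
  cfg <- augmentation_config() # reference ranges
  a <- augment(img, cfg, seed_rng(5))
  b <- augment(img, cfg, seed_rng(5))
  expect_identical(a, b)
  expect_equal(dim(a), dim(img))
  expect_true(all(a >= 0 & a <= 1))
  # sampled rotation angles stay within +/- 5 degrees
  rng <- seed_rng(11)
  for (i in 1:50) {
    pars <- tokenmixer:::draw_augment_params(cfg, rng)
    expect_lte(abs(pars$angle), 5 * pi / 180)
    expect_lte(abs(pars$dx), 0.1)
    expect_lte(abs(pars$dy), 0.1)
    expect_lte(abs(pars$zoom - 1), 0.001)
  }
  expect_error(augmentation_config(-1), ">= 0")
})

test_that("pixel loading round-trips PNG images into [0,1] tensors", {
  d <- withr::local_tempdir()
  img <- tiny_image(32, 48, seed = 9)
  png::writePNG(img, file.path(d, "a.png"))
  recs <- data.frame(path = file.path(d, "a.png"), magnification = 40L,
                     subtype = "FI", label_binary = "benign")
  x <- load_pixels(recs, size = 16L)
  expect_equal(dim(x), c(1L, 16L, 16L, 3L))
  expect_true(all(x >= 0 & x <= 1))
  # orientation: a horizontal gradient stays horizontal through the roundtrip
  grad <- array(rep(seq(0, 1, length.out = 48), each = 32), c(32, 48, 3))
  png::writePNG(grad, file.path(d, "g.png"))
  g <- tokenmixer:::load_image(file.path(d, "g.png"))
  expect_equal(dim(g), c(32L, 48L, 3L))
  expect_lt(max(abs(g - grad)), 0.01)
})
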