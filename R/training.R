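# Training and evaluation harness: Adam minibatch optimization with
# on-the-fly augmentation of the training partition only, per-epoch history,
# wall-clock timing accounting, and stratified threefold cross-validation
# for the multi-class task.

#' Training configuration
#'
#' Defaults: batch size 32, 100 epochs, Adam, learning rate 1e-3 (the
#' optimizer's common default; only the optimizer is prescribed), loss
#' matched to the model head (binary or categorical cross-entropy).
#'
#' @param batch_size minibatch size.
#' @param epochs number of epochs.
#' @param learning_rate Adam step size.
#' @param seed integer seed driving shuffling and augmentation.
#' @param loss `"auto"`, `"binary_crossentropy"` or
#'   `"categorical_crossentropy"`.
#' @return a `train_config` list.
#' @export
train_config <- function(batch_size = 32L, epochs = 100L, learning_rate = 1e-3,
                         seed = 1L, loss = c("auto", "binary_crossentropy",
                                             "categorical_crossentropy")) {
  structure(list(batch_size = as.integer(batch_size), epochs = as.integer(epochs),
                 optimizer = "adam", learning_rate = learning_rate,
                 seed = as.integer(seed), loss = match.arg(loss)),
            class = "train_config")
}

# Integer labels for a task: binary benign=0/malignant=1; multi 0..7 in the
# canonical subtype order.
labels_for <- function(records, task = c("binary", "multi")) {
  task <- match.arg(task)
  if (task == "binary") {
    as.integer(records$label_binary == "malignant")
  } else {
    match(records$subtype, SUBTYPES) - 1L
  }
}

#' Stratified fold assignment
#'
#' Assigns each record to one of `k` folds so that every class is spread
#' across folds as evenly as possible (per-class counts within 1 of n_c/k).
#'
#' @param y integer label vector.
#' @param k number of folds.
#' @param seed integer seed.
#' @return integer vector of fold ids in `1:k`.
#' @export
stratified_folds <- function(y, k = 3L, seed = 1L) {
  rng <- seed_rng(seed)
  fold_of <- integer(length(y))
  for (cl in sort(unique(y))) {
    ids <- which(y == cl)
    if (length(ids) < k) stop("class ", cl, " has fewer than ", k, " records")
    ids <- ids[rng$sample_int(length(ids))]
    fold_of[ids] <- rep_len(seq_len(k), length(ids))
  }
  fold_of
}

adam_state <- function(model) {
  st <- new.env(parent = emptyenv())
  st$t <- 0L
  st$m <- lapply(model$ps$params, function(p) array(0, dim(p$value) %||% length(p$value)))
  st$v <- st$m
  st
}

adam_step <- function(model, st, lr, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  st$t <- st$t + 1L
  b1t <- 1 - beta1^st$t
  b2t <- 1 - beta2^st$t
  for (nm in names(model$ps$params)) {
    p <- model$ps$params[[nm]]
    if (is.null(p$grad)) next
    st$m[[nm]] <- beta1 * st$m[[nm]] + (1 - beta1) * p$grad
    st$v[[nm]] <- beta2 * st$v[[nm]] + (1 - beta2) * p$grad^2
    p$value <- p$value - lr * (st$m[[nm]] / b1t) / (sqrt(st$v[[nm]] / b2t) + eps)
    p$grad <- NULL
  }
  invisible(NULL)
}

batch_loss <- function(model, xb, yb, training) {
  logits <- model$forward(xb, training = training)
  if (model$head_type == "sigmoid") {
    loss <- ad_sigmoid_bce(logits, yb)
    pred <- as.integer(as.vector(ad_value(logits)) > 0)
  } else {
    onehot <- diag(model$n_classes)[yb + 1L, , drop = FALSE]
    loss <- ad_softmax_crossentropy(logits, onehot)
    pred <- max.col(ad_value(logits), ties.method = "first") - 1L
  }
  list(loss = loss, acc = mean(pred == yb))
}

#' Train a model on a dataset split
#'
#' Runs minibatch Adam with on-the-fly augmentation of the training
#' partition only. Records per-epoch train/validation loss and accuracy and
#' wall-clock timing (total training time and its per-epoch average).
#'
#' @param model a `tm_model` whose head matches the task's label cardinality.
#' @param split a `dataset_split` (or a list with elements `x_train`,
#'   `y_train` and optionally `x_val`, `y_val` of pre-loaded tensors).
#' @param config a [train_config()].
#' @param aug an [augmentation_config()]; use zero ranges to disable.
#' @param task `"binary"` or `"multi"` (ignored for pre-loaded tensors).
#' @return list with `history` (data.frame) and `timing` (a `timing_report`).
#' @export
train <- function(model, split, config = train_config(),
                  aug = augmentation_config(), task = c("binary", "multi")) {
  task <- match.arg(task)
  if (inherits(split, "dataset_split")) {
    y_train <- labels_for(split$train, task)
    y_val <- if (nrow(split$validation) > 0) labels_for(split$validation, task) else NULL
    check_head(model, task)
    x_train <- load_pixels(split$train, model$config$image_size)
    x_val <- if (!is.null(y_val)) load_pixels(split$validation, model$config$image_size) else NULL
  } else {
    x_train <- split$x_train; y_train <- split$y_train
    x_val <- split$x_val; y_val <- split$y_val
    check_labels(model, y_train)
  }
  n <- length(y_train)
  rng <- seed_rng(config$seed)
  st <- adam_state(model)
  hist <- vector("list", config$epochs)
  start_time <- Sys.time()
  for (ep in seq_len(config$epochs)) {
    ord <- rng$sample_int(n)
    tot_loss <- 0; tot_acc <- 0; nb <- 0L
    for (bs in split(ord, ceiling(seq_along(ord) / config$batch_size))) {
      xb <- x_train[bs, , , , drop = FALSE]
      if (any_augmentation(aug)) {
        for (i in seq_along(bs)) xb[i, , , ] <- augment(xb[i, , , ], aug, rng)
      }
      res <- batch_loss(model, xb, y_train[bs], training = TRUE)
      ad_backward(res$loss)
      adam_step(model, st, config$learning_rate)
      tot_loss <- tot_loss + ad_value(res$loss) * length(bs)
      tot_acc <- tot_acc + res$acc * length(bs)
      nb <- nb + length(bs)
    }
    row <- data.frame(epoch = ep, loss = tot_loss / nb, accuracy = tot_acc / nb,
                      val_loss = NA_real_, val_accuracy = NA_real_)
    if (!is.null(x_val)) {
      vres <- batch_loss(model, x_val, y_val, training = FALSE)
      row$val_loss <- ad_value(vres$loss)
      row$val_accuracy <- vres$acc
    }
    hist[[ep]] <- row
  }
  end_time <- Sys.time()
  list(history = do.call(rbind, hist),
       timing = timing_report(start_time, end_time, config$epochs))
}

any_augmentation <- function(aug) {
  aug$rotation_range_deg > 0 || aug$width_shift_frac > 0 ||
    aug$height_shift_frac > 0 || aug$zoom_range > 0
}

check_head <- function(model, task) {
  want <- if (task == "binary") c(1L, 2L) else 8L
  if (!model$n_classes %in% want) {
    stop("model head (", model$n_classes, " unit(s)) does not match the ",
         task, " task")
  }
}

check_labels <- function(model, y) {
  k <- length(unique(y))
  if (model$head_type == "sigmoid" && k > 2) {
    stop("sigmoid head cannot fit ", k, " classes")
  }
  if (model$head_type == "softmax" && k > model$n_classes) {
    stop("model head (", model$n_classes, " units) does not match ", k, " classes")
  }
}

#' Wall-clock timing report
#'
#' `total_training_time_s = end - start`;
#' `avg_time_per_epoch_s = total / num_epochs` (exact identity).
#'
#' @param start_time,end_time POSIXct stamps.
#' @param num_epochs epochs covered.
#' @return a `timing_report` list.
#' @export
timing_report <- function(start_time, end_time, num_epochs) {
  total <- as.numeric(difftime(end_time, start_time, units = "secs"))
  structure(list(start_time = start_time, end_time = end_time,
                 total_training_time_s = total,
                 avg_time_per_epoch_s = total / num_epochs,
                 num_epochs = as.integer(num_epochs)),
            class = "timing_report")
}

#' Evaluate a model on labeled records
#'
#' Runs inference and assembles the evaluation report: confusion matrix,
#' rate metrics, MCC, kappa, both G-mean variants, and ROC/AUC from the
#' predicted scores (one-vs-rest macro average for the multi-class task).
#'
#' @param model a `tm_model`.
#' @param records record data.frame (or list with `x`, `y`).
#' @param task `"binary"` or `"multi"`.
#' @return an `eval_report` list.
#' @export
evaluate <- function(model, records, task = c("binary", "multi")) {
  task <- match.arg(task)
  if (is.data.frame(records)) {
    if (nrow(records) == 0) stop("no records to evaluate")
    y <- labels_for(records, task)
    x <- load_pixels(records, model$config$image_size)
  } else {
    x <- records$x; y <- records$y
    if (is.null(x) || length(y) == 0) stop("no records to evaluate")
  }
  probs <- model_predict(model, x)
  if (model$head_type == "sigmoid") {
    scores <- as.vector(probs)
    pred <- as.integer(scores > 0.5)
    K <- 2L
  } else {
    pred <- max.col(probs, ties.method = "first") - 1L
    K <- model$n_classes
    scores <- if (K == 2L) probs[, 2] else probs
  }
  cm <- confusion(y, pred, K = K)
  report <- list(confusion = cm, n = length(y), task = task)
  if (K == 2L) {
    rm_ <- rate_metrics(cm)
    roc <- tryCatch(roc_auc(y, scores), error = function(e) NULL)
    report$metrics <- c(rm_[c("accuracy", "sensitivity", "precision", "specificity", "f1")],
                        list(auc = if (is.null(roc)) NA_real_ else roc$auc,
                             mcc = mcc(cm)$mcc, kappa = kappa_stat(cm)$kappa),
                        gmean(rm_$precision, rm_$sensitivity,
                              rm_$sensitivity, rm_$specificity)[
                                c("g_precision_recall", "g_sens_spec")])
    report$roc <- roc$roc
  } else {
    mr <- multiclass_report(cm)
    aucs <- vapply(seq_len(K) - 1L, function(k) {
      if (length(unique(y == k)) < 2) return(NA_real_)
      roc_auc(as.integer(y == k), probs[, k + 1L])$auc
    }, numeric(1))
    mr$auc_macro <- mean(aucs, na.rm = TRUE)
    report$metrics <- mr
  }
  class(report) <- "eval_report"
  report
}

#' Stratified threefold cross-validation
#'
#' Partitions the records into three stratified folds, trains a fresh model
#' per fold on the other two and evaluates on the held-out fold. The three
#' validation folds are pairwise disjoint and cover the pool.
#'
#' @param records record data.frame (>= 3 per class) or a list with `x`, `y`.
#' @param builder function(seed) returning a fresh `tm_model`.
#' @param config a [train_config()].
#' @param aug an [augmentation_config()].
#' @param task `"binary"` or `"multi"`.
#' @return list with `folds` (per-fold index/report), `mean` and `sd` of the
#'   headline metrics.
#' @export
crossvalidate_3fold <- function(records, builder, config = train_config(),
                                aug = augmentation_config(),
                                task = c("binary", "multi")) {
  task <- match.arg(task)
  tensors <- !is.data.frame(records)
  y <- if (tensors) records$y else labels_for(records, task)
  n <- length(y)
  fold_of <- stratified_folds(y, 3L, config$seed)
  folds <- lapply(1:3, function(f) {
    val_idx <- which(fold_of == f)
    tr_idx <- which(fold_of != f)
    model <- builder(derive_seed(config$seed, f))
    if (tensors) {
      tr <- list(x_train = records$x[tr_idx, , , , drop = FALSE], y_train = y[tr_idx])
      fit <- train(model, tr, config, aug, task)
      rep_ <- evaluate(model, list(x = records$x[val_idx, , , , drop = FALSE],
                                   y = y[val_idx]), task)
    } else {
      tr <- list(x_train = load_pixels(records[tr_idx, , drop = FALSE],
                                       model$config$image_size), y_train = y[tr_idx])
      fit <- train(model, tr, config, aug, task)
      rep_ <- evaluate(model, records[val_idx, , drop = FALSE], task)
    }
    list(fold = f - 1L, val_idx = val_idx, history = fit$history,
         timing = fit$timing, report = rep_)
  })
  acc <- vapply(folds, function(f) {
    m <- f$report$metrics
    if (!is.null(m$accuracy)) m$accuracy else m$micro$accuracy
  }, numeric(1))
  list(folds = folds, mean = list(accuracy = mean(acc)), sd = list(accuracy = stats::sd(acc)))
}
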