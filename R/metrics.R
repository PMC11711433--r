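# Classification metric suite: confusion matrices, the rate metrics,
# Matthews correlation, Cohen's kappa, both G-mean variants, and ROC/AUC.
# Undefined ratios are reported as 0 with a `flags` entry rather than
# raising, so batch evaluation stays total.

#' Confusion matrix from label vectors
#'
#' @param y_true,y_pred equal-length integer vectors with values in
#'   `0:(K-1)`.
#' @param K number of classes (default: inferred).
#' @return `K x K` integer matrix, rows = true class, cols = predicted.
#' @export
confusion <- function(y_true, y_pred, K = max(y_true, y_pred) + 1L) {
  if (length(y_true) != length(y_pred)) stop("label vectors must have equal length")
  if (any(c(y_true, y_pred) < 0) || any(c(y_true, y_pred) >= K)) {
    stop("labels must lie in [0, K)")
  }
  cm <- matrix(0L, K, K)
  for (i in seq_along(y_true)) {
    cm[y_true[i] + 1L, y_pred[i] + 1L] <- cm[y_true[i] + 1L, y_pred[i] + 1L] + 1L
  }
  dimnames(cm) <- list(true = 0:(K - 1L), pred = 0:(K - 1L))
  cm
}

# Binary counts from a 2x2 confusion matrix; class 1 is "positive"
# (malignant). Rows = true, cols = predicted.
binary_counts <- function(cm) {
  stopifnot(all(dim(cm) == 2L))
  list(tp = cm[2, 2], tn = cm[1, 1], fp = cm[1, 2], fn = cm[2, 1])
}

safe_ratio <- function(num, den, flags, what) {
  if (den == 0) {
    flags[[length(flags) + 1L]] <- what
    list(value = 0, flags = flags)
  } else {
    list(value = num / den, flags = flags)
  }
}

#' Rate metrics of a binary confusion matrix
#'
#' Accuracy, sensitivity (recall), precision, specificity and F1, exactly as
#' conventionally defined from TP/TN/FP/FN. Zero denominators yield a
#' flagged 0.
#'
#' @param cm `2 x 2` confusion matrix (rows = true, cols = predicted,
#'   class 1 = positive).
#' @return list with the five rates and a `flags` character vector.
#' @export
rate_metrics <- function(cm) {
  b <- binary_counts(cm)
  flags <- list()
  r <- safe_ratio(b$tp + b$tn, b$tp + b$tn + b$fp + b$fn, flags, "accuracy"); acc <- r$value; flags <- r$flags
  r <- safe_ratio(b$tp, b$tp + b$fn, flags, "sensitivity"); sens <- r$value; flags <- r$flags
  r <- safe_ratio(b$tp, b$tp + b$fp, flags, "precision"); prec <- r$value; flags <- r$flags
  r <- safe_ratio(b$tn, b$tn + b$fp, flags, "specificity"); spec <- r$value; flags <- r$flags
  r <- safe_ratio(2 * prec * sens, prec + sens, flags, "f1"); f1 <- r$value; flags <- r$flags
  list(accuracy = acc, sensitivity = sens, precision = prec,
       specificity = spec, f1 = f1, flags = unlist(flags))
}

#' Matthews correlation coefficient
#'
#' Binary 2x2 input uses the classical four-count formula; a `K x K` input
#' uses the generalized multi-class form. Bounded in `[-1, 1]`; a zero
#' denominator yields a flagged 0.
#'
#' @param cm confusion matrix.
#' @return list with `mcc` and `flags`.
#' @export
mcc <- function(cm) {
  if (all(dim(cm) == 2L)) {
    b <- binary_counts(cm)
    den <- sqrt(b$tp + b$fp) * sqrt(b$tp + b$fn) * sqrt(b$tn + b$fp) * sqrt(b$tn + b$fn)
    if (den == 0) return(list(mcc = 0, flags = "mcc"))
    return(list(mcc = (b$tp * b$tn - b$fp * b$fn) / den, flags = character(0)))
  }
  n <- sum(cm)
  tr <- sum(diag(cm))
  rowm <- rowSums(cm); colm <- colSums(cm)
  num <- tr * n - sum(rowm * colm)
  den <- sqrt(n^2 - sum(colm^2)) * sqrt(n^2 - sum(rowm^2))
  if (den == 0) return(list(mcc = 0, flags = "mcc"))
  list(mcc = num / den, flags = character(0))
}

#' Cohen's kappa (chance-corrected agreement)
#'
#' `Po = trace / n`, `Pe = sum_c(row_c * col_c) / n^2`,
#' `kappa = (Po - Pe) / (1 - Pe)`.
#'
#' @param cm square confusion matrix.
#' @return list with `po`, `pe`, `kappa` and `flags`.
#' @export
kappa_stat <- function(cm) {
  if (nrow(cm) != ncol(cm)) stop("confusion matrix must be square")
  n <- sum(cm)
  po <- sum(diag(cm)) / n
  pe <- sum(rowSums(cm) * colSums(cm)) / n^2
  if (pe == 1) return(list(po = po, pe = pe, kappa = 0, flags = "kappa"))
  list(po = po, pe = pe, kappa = (po - pe) / (1 - pe), flags = character(0))
}

#' Two G-mean variants
#'
#' `g_precision_recall = sqrt(precision * recall / (precision + recall))`
#' (note its maximum is `sqrt(1/2)`, not 1), and the conventional
#' `g_sens_spec = sqrt(sensitivity * specificity)`. Both are reported.
#'
#' @param precision,recall,sensitivity,specificity rates in `[0, 1]`.
#' @return list with `g_precision_recall`, `g_sens_spec` and `flags`.
#' @export
gmean <- function(precision, recall, sensitivity = recall, specificity) {
  flags <- character(0)
  if (precision + recall == 0) {
    gpr <- 0; flags <- "g_precision_recall"
  } else {
    gpr <- sqrt(precision * recall / (precision + recall))
  }
  list(g_precision_recall = gpr,
       g_sens_spec = sqrt(sensitivity * specificity),
       flags = flags)
}

#' ROC curve and trapezoidal AUC
#'
#' Threshold sweep over the unique scores (plus sentinels); reports the ROC
#' points, the trapezoidal AUC, and the sensitivity/specificity ratio at the
#' 0.5 threshold as a secondary diagnostic.
#'
#' @param y_true binary labels (0/1).
#' @param scores continuous scores, higher = more positive.
#' @return list with `roc` (data.frame fpr/tpr/threshold), `auc`, and
#'   `sens_spec_ratio_at_half`.
#' @export
roc_auc <- function(y_true, scores) {
  if (length(unique(y_true)) < 2) stop("need both classes in y_true")
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE), -Inf)
  P <- sum(y_true == 1); N <- sum(y_true == 0)
  tpr <- fpr <- numeric(length(thr))
  for (i in seq_along(thr)) {
    pred <- scores >= thr[i]
    tpr[i] <- sum(pred & y_true == 1) / P
    fpr[i] <- sum(pred & y_true == 0) / N
  }
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  pred_half <- as.integer(scores >= 0.5)
  cm <- confusion(y_true, pred_half, K = 2L)
  rm_ <- rate_metrics(cm)
  ratio <- if (rm_$specificity == 0) Inf else rm_$sensitivity / rm_$specificity
  list(roc = data.frame(fpr = fpr, tpr = tpr, threshold = thr),
       auc = auc, sens_spec_ratio_at_half = ratio)
}

#' Full metric report for a K-way confusion matrix
#'
#' Per-class one-vs-rest rates plus macro (unweighted mean) and micro
#' (pooled) aggregates, the generalized MCC, and kappa on the K x K table.
#'
#' @param cm `K x K` confusion matrix (K >= 2).
#' @return list with `per_class` (data.frame), `macro`, `micro`, `mcc`,
#'   `kappa`, `accuracy`.
#' @export
multiclass_report <- function(cm) {
  K <- nrow(cm)
  if (K < 2) stop("need at least two classes")
  n <- sum(cm)
  per <- lapply(seq_len(K), function(k) {
    tp <- cm[k, k]
    fn <- sum(cm[k, -k])
    fp <- sum(cm[-k, k])
    tn <- n - tp - fn - fp
    rate_metrics(matrix(c(tn, fn, fp, tp), 2, 2))
  })
  per_df <- data.frame(
    class = seq_len(K) - 1L,
    precision = vapply(per, `[[`, numeric(1), "precision"),
    sensitivity = vapply(per, `[[`, numeric(1), "sensitivity"),
    specificity = vapply(per, `[[`, numeric(1), "specificity"),
    f1 = vapply(per, `[[`, numeric(1), "f1")
  )
  # micro aggregates pool the one-vs-rest counts; for single-label tasks
  # micro precision = micro recall = overall accuracy
  tp_sum <- sum(diag(cm))
  fp_sum <- sum(cm) - tp_sum
  micro_prec <- tp_sum / (tp_sum + fp_sum)
  list(per_class = per_df,
       macro = list(precision = mean(per_df$precision),
                    sensitivity = mean(per_df$sensitivity),
                    specificity = mean(per_df$specificity),
                    f1 = mean(per_df$f1)),
       micro = list(precision = micro_prec, sensitivity = micro_prec,
                    accuracy = tp_sum / n),
       mcc = mcc(cm)$mcc,
       kappa = kappa_stat(cm)$kappa,
       accuracy = tp_sum / n)
}
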