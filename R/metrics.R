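#' Segmentation metrics over pixel sets
#'
#' With ground-truth lesion pixel set `A_g` and predicted set `A_p`:
#' `DSC = 2|Ag n Ap| / (|Ag| + |Ap|)`, `JI = |Ag n Ap| / |Ag u Ap|`,
#' `TPR = |Ag n Ap| / |Ag|`, `FPR = |(Ag u Ap) \ Ag| / |Ag u Ap|`, and
#' the tumour-normalised false positive rate
#' `tFPR = |(Ag u Ap) \ Ag| / |Ag|`, which can exceed 1.
#'
#' Empty-set conventions: both sets empty gives dsc = ji = tpr = 1 and
#' fpr = tfpr = 0 (a correctly empty prediction); `A_g` empty with a
#' non-empty prediction gives dsc = ji = tpr = 0, fpr = 1, and tfpr = NA
#' (that image is excluded from tFPR averages and counted by callers).
#'
#' @param pred_mask,true_mask binary (0/1 or logical) matrices of equal
#'   shape.
#' @return List of class `"seg_metrics"`: `dsc`, `ji`, `tpr`, `fpr`,
#'   `tfpr`.
#' @export
#' @examples
#' g <- matrix(0, 20, 20); g[1:10, 1:10] <- 1
#' p <- matrix(0, 20, 20); p[1:10, 3:10] <- 1
#' seg_metrics(p, g)$dsc
seg_metrics <- function(pred_mask, true_mask) {
  if (!all(dim(pred_mask) == dim(true_mask)))
    stop("mask shape mismatch")
  p <- pred_mask != 0
  g <- true_mask != 0
  np <- sum(p); ng <- sum(g)
  inter <- sum(p & g)
  uni <- np + ng - inter
  fp <- uni - ng  # |(Ag u Ap) \ Ag| = |Ap \ Ag|
  out <- if (ng == 0L && np == 0L) {
    list(dsc = 1, ji = 1, tpr = 1, fpr = 0, tfpr = 0)
  } else if (ng == 0L) {
    list(dsc = 0, ji = 0, tpr = 0, fpr = 1, tfpr = NA_real_)
  } else {
    list(dsc = 2 * inter / (ng + np),
         ji = if (uni > 0) inter / uni else 1,
         tpr = inter / ng,
         fpr = if (uni > 0) fp / uni else 0,
         tfpr = fp / ng)
  }
  structure(out, class = "seg_metrics")
}

#' Classification metrics
#'
#' Confusion counts at the given score threshold and the formula-exact
#' accuracy, sensitivity, specificity, precision and F1; AUC by the
#' rank-based Mann-Whitney statistic with midrank tie handling.
#'
#' @param scores per-image positive-class scores.
#' @param labels binary labels (0 = negative/normal, 1 = positive/lesion).
#' @param threshold score threshold for the confusion counts (default
#'   0.5).
#' @return List of class `"cls_metrics"`: `auc`, `acc`, `sen`, `spc`,
#'   `pre`, `f1`, and counts `tp`, `tn`, `fp`, `fn`. With a degenerate
#'   label set (only one class present) `auc` is NA with a warning; the
#'   threshold metrics are still returned.
#' @export
cls_metrics <- function(scores, labels, threshold = 0.5) {
  stopifnot(length(scores) == length(labels))
  labels <- as.integer(labels != 0)
  pred <- as.integer(scores >= threshold)
  tp <- sum(pred == 1L & labels == 1L)
  tn <- sum(pred == 0L & labels == 0L)
  fp <- sum(pred == 1L & labels == 0L)
  fn <- sum(pred == 0L & labels == 1L)
  n1 <- sum(labels == 1L); n0 <- sum(labels == 0L)
  auc <- if (n1 == 0L || n0 == 0L) {
    warning("AUC undefined: need at least one positive and one negative")
    NA_real_
  } else {
    r <- rank(scores)  # midranks
    (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  }
  sen <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  spc <- if (tn + fp > 0) tn / (tn + fp) else NA_real_
  pre <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
  f1 <- if (!is.na(pre) && !is.na(sen) && pre + sen > 0)
    2 * pre * sen / (pre + sen) else NA_real_
  structure(list(auc = auc,
                 acc = (tp + tn) / length(labels),
                 sen = sen, spc = spc, pre = pre, f1 = f1,
                 tp = tp, tn = tn, fp = fp, fn = fn),
            class = "cls_metrics")
}

#' Aggregate per-image metrics into a summary row
#'
#' Segmentation metrics are averaged per image (unweighted); images whose
#' tFPR is undefined (empty ground truth, non-empty prediction) are
#' excluded from the tFPR mean and counted. Classification metrics are
#' computed once over the pooled scores.
#'
#' @param seg list of `"seg_metrics"` (one per image), or `NULL`.
#' @param scores,labels pooled classification scores and binary labels,
#'   or `NULL`.
#' @param threshold classification threshold.
#' @return One-row data.frame with columns
#'   `dsc, ji, tpr, fpr, tfpr, auc, acc, sen, spc, pre, f1` and
#'   `n_tfpr_excluded`.
#' @export
aggregate_metrics <- function(seg = NULL, scores = NULL, labels = NULL,
                              threshold = 0.5) {
  if (is.null(seg) && is.null(scores)) stop("nothing to aggregate")
  segrow <- c(dsc = NA_real_, ji = NA_real_, tpr = NA_real_,
              fpr = NA_real_, tfpr = NA_real_)
  nexcl <- 0L
  if (!is.null(seg)) {
    if (!length(seg)) stop("empty metric list")
    m <- vapply(seg, function(s)
      c(s$dsc, s$ji, s$tpr, s$fpr, s$tfpr), numeric(5))
    nexcl <- sum(is.na(m[5, ]))
    segrow <- c(dsc = mean(m[1, ]), ji = mean(m[2, ]), tpr = mean(m[3, ]),
                fpr = mean(m[4, ]), tfpr = mean(m[5, ], na.rm = TRUE))
  }
  clsrow <- c(auc = NA_real_, acc = NA_real_, sen = NA_real_,
              spc = NA_real_, pre = NA_real_, f1 = NA_real_)
  if (!is.null(scores)) {
    cm <- cls_metrics(scores, labels, threshold)
    clsrow <- c(auc = cm$auc, acc = cm$acc, sen = cm$sen, spc = cm$spc,
                pre = cm$pre, f1 = cm$f1)
  }
  cbind(as.data.frame(as.list(segrow)), as.data.frame(as.list(clsrow)),
        n_tfpr_excluded = nexcl)
}
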