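#' Soft Dice segmentation loss
#'
#' Per-class soft Dice `(2 * sum(p*t) + eps) / (sum(p) + sum(t) + eps)`
#' with `eps = 1`, averaged over classes; the loss is one minus that
#' mean. The smoothing term guards empty classes (empty-vs-empty gives
#' Dice 1) and suits the strong class imbalance of lesion segmentation.
#'
#' @param pred per-class probability map, C x H x W array (or C x N
#'   matrix), per-pixel normalised.
#' @param target one-hot label map of the same shape.
#' @param eps smoothing constant (default 1).
#' @return Scalar loss in \[0, 1\].
#' @export
#' @examples
#' t <- array(0, c(2, 8, 8)); t[1, 1:4, ] <- 1; t[2, , ] <- 1 - t[1, , ]
#' dice_loss(t, t)  # ~0
dice_loss <- function(pred, target, eps = 1) {
  if (!all(dim(pred) == dim(target))) stop("pred/target shape mismatch")
  p <- if (length(dim(pred)) == 3L) arr3_to_mat(pred) else pred
  t <- if (length(dim(target)) == 3L) arr3_to_mat(target) else target
  dice_loss_grad(p, t, 1L, eps = eps)$loss
}

#' Classification cross-entropy loss
#'
#' `-log h_score[label]`, averaged over a batch when given a matrix of
#' scores.
#'
#' @param pred a `"class_prediction"`, a length-C score vector, or a
#'   C x B score matrix.
#' @param label 0-based class index (vector of length B for a batch).
#' @return Scalar loss.
#' @export
cls_loss <- function(pred, label) {
  h <- if (inherits(pred, "class_prediction")) pred$h_score else pred
  if (is.matrix(h)) {
    if (any(label < 0 | label >= nrow(h))) stop("label out of range")
    mean(-log(h[cbind(label + 1L, seq_len(ncol(h)))]))
  } else {
    if (label < 0 || label >= length(h)) stop("label out of range")
    -log(h[label + 1L])
  }
}

#' Task-weight state for dynamic weight averaging
#'
#' @param temperature softness of the task weighting (default 2).
#' @param num_tasks number of tasks K (2: classification, segmentation).
#' @return Object of class `"task_weight_state"` with an empty loss
#'   history and unit weights.
#' @export
task_weight_state <- function(temperature = 2, num_tasks = 2L) {
  structure(list(loss_history = vector("list", num_tasks),
                 weights = rep(1, num_tasks),
                 temperature = temperature,
                 num_tasks = as.integer(num_tasks)),
            class = "task_weight_state")
}

#' Dynamic weight averaging update
#'
#' For epoch `t <= 2` all weights are 1; afterwards
#' `w_k = L_k(t-1) / L_k(t-2)` and
#' `lambda_k = K * exp(w_k / T) / sum_i exp(w_i / T)`, so the weights
#' always sum to K. `loss_history` must hold the epoch-mean loss of each
#' task for all completed epochs.
#'
#' @param state a `"task_weight_state"`.
#' @param epoch the (1-based) epoch about to run.
#' @return The state with `weights` updated.
#' @export
#' @examples
#' st <- task_weight_state()
#' st$loss_history <- list(c(1.0, 0.8), c(0.6, 0.54))
#' dwa_update(st, 3)$weights
dwa_update <- function(state, epoch) {
  stopifnot(inherits(state, "task_weight_state"))
  K <- state$num_tasks
  if (epoch <= 2) {
    state$weights <- rep(1, K)
    return(state)
  }
  w <- vapply(state$loss_history, function(hist) {
    if (length(hist) < epoch - 1L)
      stop("loss history is missing completed epochs")
    l1 <- hist[epoch - 1L]; l2 <- hist[epoch - 2L]
    if (!is.finite(l1) || !is.finite(l2) || l1 <= 0 || l2 <= 0)
      stop("nonpositive or non-finite historical loss in DWA update")
    l1 / l2
  }, numeric(1))
  e <- exp(w / state$temperature)
  state$weights <- K * e / sum(e)
  state
}

#' Joint multi-task loss
#'
#' `l_total = lambda_1 * l_cls + lambda_2 * (l_cseg + l_fseg)`: one
#' cross-entropy term for classification and the two Dice terms for the
#' coarse and fine segmentation units sharing the second task weight.
#'
#' @param l_cls,l_cseg,l_fseg scalar component losses.
#' @param weights a `"task_weight_state"` or a numeric vector
#'   `c(lambda_1, lambda_2)`.
#' @return List of class `"loss_bundle"` with all four scalars.
#' @export
total_loss <- function(l_cls, l_cseg, l_fseg, weights) {
  lam <- if (inherits(weights, "task_weight_state")) weights$weights
  else weights
  stopifnot(length(lam) == 2L, all(is.finite(c(l_cls, l_cseg, l_fseg))))
  structure(list(l_cls = l_cls, l_cseg = l_cseg, l_fseg = l_fseg,
                 l_total = lam[1] * l_cls + lam[2] * (l_cseg + l_fseg),
                 weights = lam),
            class = "loss_bundle")
}
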