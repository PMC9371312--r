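# Training (the end-to-end optimisation loop): forward through
# encoder+ASPP -> coarse decoder -> classifier (LAM) -> fine decoder
# (CSM+AKGM), joint loss l1*CE + l2*(Dice_coarse + Dice_fine) with
# dynamic weight averaging per epoch, Adam updates, early stopping on
# the weighted validation loss.

samples_to_tensors <- function(samples) {
  H <- nrow(samples[[1]]$image); W <- ncol(samples[[1]]$image)
  N <- H * W
  X <- matrix(0, 1L, N * length(samples))
  Tc <- matrix(0, 3L, N * length(samples))
  Tf <- matrix(0, 2L, N * length(samples))
  labs <- integer(length(samples))
  for (i in seq_along(samples)) {
    s <- samples[[i]]
    cols <- (i - 1L) * N + seq_len(N)
    X[, cols] <- as.numeric(s$image)
    cm <- as.integer(s$coarse_mask)
    Tc[1L, cols] <- as.numeric(cm == 2L)
    Tc[2L, cols] <- as.numeric(cm == 1L)
    Tc[3L, cols] <- as.numeric(cm == 0L)
    lm <- as.numeric(s$lesion_mask)
    Tf[1L, cols] <- lm
    Tf[2L, cols] <- 1 - lm
    labs[i] <- s$class_label
  }
  list(X = X, Tc = Tc, Tf = Tf, labels = labs, H = H, W = W, N = N)
}

batch_cols <- function(idx, N) {
  as.vector(vapply(idx, function(i) (i - 1L) * N + seq_len(N),
                   integer(N)))
}

step_losses <- function(p, cfg, td, idx, lam, with_grads = TRUE) {
  N <- td$N; B <- length(idx)
  cols <- batch_cols(idx, N)
  fwd <- ctg_forward(p, cfg, td$X[, cols, drop = FALSE], td$H, td$W, B)
  ce <- ce_loss_grad(fwd$cls$h, td$labels[idx] + 1L, B)
  # the training Dice is pooled over the batch (one soft Dice per class on
  # the concatenated pixels): per-image Dice with the smoothing term makes
  # "predict empty" a strong attractor on lesion-free images, whose
  # per-pixel gradients then dwarf those of lesion images and collapse the
  # lesion channel; pooling balances the two. Evaluation metrics remain
  # per-image.
  dc <- dice_loss_grad(fwd$Mprobs, td$Tc[, cols, drop = FALSE], 1L)
  df <- dice_loss_grad(fwd$Fprobs, td$Tf[, cols, drop = FALSE], 1L)
  out <- list(l_cls = ce$loss, l_cseg = dc$loss, l_fseg = df$loss,
              l_total = lam[1] * ce$loss + lam[2] * (dc$loss + df$loss),
              fwd = fwd)
  if (with_grads) {
    out$grads <- ctg_backward(p, cfg, fwd, lam[1] * ce$dlogits,
                              lam[2] * dc$grad, lam[2] * df$grad)
  }
  out
}

eval_losses <- function(p, cfg, td, lam, batch_size = 8L) {
  n <- length(td$labels)
  tot <- c(l_cls = 0, l_cseg = 0, l_fseg = 0)
  correct <- 0L
  dscs <- numeric(0)
  for (start in seq(1L, n, by = batch_size)) {
    idx <- start:min(n, start + batch_size - 1L)
    st <- step_losses(p, cfg, td, idx, lam, with_grads = FALSE)
    wb <- length(idx) / n
    tot <- tot + wb * c(st$l_cls, st$l_cseg, st$l_fseg)
    pred_lab <- max.col(t(st$fwd$cls$h)) - 1L
    correct <- correct + sum(pred_lab == td$labels[idx])
    for (j in seq_along(idx)) {
      cols <- (j - 1L) * td$N + seq_len(td$N)
      pm <- st$fwd$Fprobs[1L, cols] >= 0.5
      gm <- td$Tf[1L, batch_cols(idx[j], td$N)] > 0.5
      if (any(gm)) dscs <- c(dscs, 2 * sum(pm & gm) / (sum(pm) + sum(gm)))
    }
  }
  list(l_cls = tot[["l_cls"]], l_cseg = tot[["l_cseg"]],
       l_fseg = tot[["l_fseg"]],
       l_total = lam[1] * tot[["l_cls"]] +
         lam[2] * (tot[["l_cseg"]] + tot[["l_fseg"]]),
       acc = correct / n,
       dsc = if (length(dscs)) mean(dscs) else NA_real_)
}

#' Fit the cross-task guided network
#'
#' Trains the joint segmentation + classification network on phantom (or
#' phantom-shaped) samples: Adam optimisation of the joint loss
#' `lambda_1 * L_cls + lambda_2 * (L_cseg + L_fseg)` with per-epoch
#' dynamic weight averaging (temperature 2) and early stopping when the
#' weighted validation loss has not improved for `patience` consecutive
#' epochs. The best-validation parameters are kept.
#'
#' @param x list of `"phantom_sample"` training data (see
#'   [generate_dataset()] / [read_dataset()]).
#' @param val optional validation samples; without them the model trains
#'   for `max_epochs` and keeps the final parameters.
#' @param config a [ctg_config()].
#' @param seed integer seed controlling initialisation and shuffling.
#' @param fixed_weights optional `c(lambda_1, lambda_2)` to disable
#'   dynamic weight averaging (e.g. `c(1, 1)`).
#' @param verbose print one line per epoch.
#' @return Object of class `"ctgnet"` with elements `params` (best
#'   parameters), `config`, `log` (per-epoch data.frame with losses and
#'   task weights), `best_epoch`, `epochs_run`, and `call`. Methods:
#'   [predict.ctgnet()], `print`, `summary`, `coef`, `plot`, `simulate`,
#'   `residuals`.
#' @export
ctgnet_fit <- function(x, val = NULL, config = ctg_config(desk_profile = TRUE),
                       seed = config$train$seed, fixed_weights = NULL,
                       verbose = FALSE) {
  validate_ctg_config(config)
  if (!length(x)) stop("empty training dataset")
  if (max(vapply(x, function(s) s$class_label, integer(1))) >=
      config$num_classes)
    stop("class labels exceed config$num_classes")
  tr <- config$train
  td <- samples_to_tensors(x)
  if (td$H != config$image_size || td$W != config$image_size)
    stop("sample size ", td$H, "x", td$W,
         " does not match config image_size ", config$image_size)
  vd <- if (!is.null(val)) samples_to_tensors(val)
  old <- local_rng(seed)
  on.exit(restore_rng(old))
  p <- ctg_init_params(config, seed)
  ad <- adam_init(p)
  tws <- task_weight_state(temperature = tr$dwa_temperature)
  n <- length(x)
  log_rows <- list()
  best <- list(loss = Inf, epoch = 0L, params = p)
  since_best <- 0L
  for (epoch in seq_len(tr$max_epochs)) {
    lam <- if (!is.null(fixed_weights)) fixed_weights
    else dwa_update(tws, epoch)$weights
    ord <- sample(n)
    ep <- c(l_cls = 0, l_cseg = 0, l_fseg = 0)
    nb <- 0L
    for (start in seq(1L, n, by = tr$batch_size)) {
      idx <- ord[start:min(n, start + tr$batch_size - 1L)]
      st <- step_losses(p, config, td, idx, lam)
      if (!is.finite(st$l_total))
        stop("non-finite loss at epoch ", epoch, ", batch ", nb + 1L)
      up <- adam_step(p, st$grads, ad, tr$learning_rate,
                      tr$adam_beta1, tr$adam_beta2, tr$adam_eps)
      p <- up$params; ad <- up$state
      ep <- ep + c(st$l_cls, st$l_cseg, st$l_fseg)
      nb <- nb + 1L
    }
    ep <- ep / nb
    tws$loss_history[[1]] <- c(tws$loss_history[[1]], ep[["l_cls"]])
    tws$loss_history[[2]] <- c(tws$loss_history[[2]],
                               ep[["l_cseg"]] + ep[["l_fseg"]])
    row <- data.frame(epoch = epoch, l_cls = ep[["l_cls"]],
                      l_cseg = ep[["l_cseg"]], l_fseg = ep[["l_fseg"]],
                      lambda1 = lam[1], lambda2 = lam[2],
                      l_total = lam[1] * ep[["l_cls"]] +
                        lam[2] * (ep[["l_cseg"]] + ep[["l_fseg"]]))
    if (!is.null(vd)) {
      ev <- eval_losses(p, config, vd, lam, tr$batch_size)
      row$val_l_total <- ev$l_total
      row$val_dsc <- ev$dsc
      row$val_acc <- ev$acc
      if (ev$l_total < best$loss) {
        best <- list(loss = ev$l_total, epoch = epoch, params = p)
        since_best <- 0L
      } else {
        since_best <- since_best + 1L
      }
    }
    log_rows[[epoch]] <- row
    if (verbose)
      cat(sprintf(
        "epoch %3d  cls %.4f  cseg %.4f  fseg %.4f  l=(%.3f,%.3f)%s\n",
        epoch, ep[["l_cls"]], ep[["l_cseg"]], ep[["l_fseg"]],
        lam[1], lam[2],
        if (!is.null(vd)) sprintf("  val %.4f", row$val_l_total) else ""))
    if (!is.null(vd) && since_best >= tr$patience) break
  }
  if (is.null(vd)) best <- list(loss = NA_real_, epoch = length(log_rows),
                                params = p)
  structure(list(params = best$params, config = config,
                 log = do.call(rbind, log_rows),
                 best_epoch = best$epoch,
                 epochs_run = length(log_rows),
                 final_params = p,
                 seed = seed,
                 phantom_config = attr(x, "phantom_config"),
                 call = match.call()),
            class = "ctgnet")
}

#' Predict segmentation masks and class scores
#'
#' Deterministic inference-mode forward pass through all three heads.
#'
#' @param object a fitted `"ctgnet"`.
#' @param newdata list of `"phantom_sample"` objects or of HxW image
#'   matrices.
#' @param type `"all"` (default) or one of `"fine"`, `"coarse"`,
#'   `"class"`.
#' @param threshold lesion-probability threshold for the hard fine mask.
#' @param batch_size images per forward pass.
#' @param ... unused.
#' @return List with `scores` (n x C matrix of class probabilities),
#'   `class` (0-based predicted labels), `fine_prob` (list of HxW lesion
#'   probability matrices), `fine_mask` (list of 0/1 matrices) and
#'   `coarse_label` (list of 0/1/2 matrices), filtered by `type`.
#' @export
predict.ctgnet <- function(object, newdata, type = "all", threshold = 0.5,
                           batch_size = 8L, ...) {
  imgs <- lapply(newdata, function(s)
    if (is.matrix(s)) s else s$image)
  H <- nrow(imgs[[1]]); W <- ncol(imgs[[1]])
  n <- length(imgs)
  p <- object$params; cfg <- object$config
  scores <- matrix(NA_real_, n, cfg$num_classes)
  fine_prob <- vector("list", n)
  fine_mask <- vector("list", n)
  coarse_label <- vector("list", n)
  N <- H * W
  for (start in seq(1L, n, by = batch_size)) {
    idx <- start:min(n, start + batch_size - 1L)
    X <- matrix(0, 1L, N * length(idx))
    for (j in seq_along(idx))
      X[, (j - 1L) * N + seq_len(N)] <- as.numeric(imgs[[idx[j]]])
    fwd <- ctg_forward(p, cfg, X, H, W, length(idx))
    scores[idx, ] <- t(fwd$cls$h)
    for (j in seq_along(idx)) {
      cols <- (j - 1L) * N + seq_len(N)
      fp <- matrix(fwd$Fprobs[1L, cols], H, W)
      fine_prob[[idx[j]]] <- fp
      fine_mask[[idx[j]]] <- matrix(as.integer(fp >= threshold), H, W)
      mp <- fwd$Mprobs[, cols, drop = FALSE]
      chan <- max.col(t(mp), ties.method = "first")
      coarse_label[[idx[j]]] <- matrix(c(2L, 1L, 0L)[chan], H, W)
    }
  }
  out <- list(scores = scores, class = max.col(scores) - 1L,
              fine_prob = fine_prob, fine_mask = fine_mask,
              coarse_label = coarse_label)
  switch(type,
         all = out,
         fine = out[c("fine_prob", "fine_mask")],
         coarse = out["coarse_label"],
         class = out[c("scores", "class")],
         stop("unknown type: ", type))
}

#' Evaluate a fitted model on labelled samples
#'
#' Runs [predict.ctgnet()] and computes per-image segmentation metrics of
#' the thresholded fine mask against the true lesion mask, plus pooled
#' classification metrics (positive class = any lesion; in three-class
#' mode the positive score is one minus the normal-class score).
#'
#' @param object a fitted `"ctgnet"`.
#' @param samples list of `"phantom_sample"` objects with ground truth.
#' @param threshold segmentation and classification threshold.
#' @return List with `summary` (one-row data.frame: dsc, ji, tpr, fpr,
#'   tfpr, auc, acc, sen, spc, pre, f1), `per_image` (list of
#'   `"seg_metrics"`), `scores` and `labels`.
#' @export
evaluate_model <- function(object, samples, threshold = 0.5) {
  pr <- predict(object, samples, threshold = threshold)
  per <- lapply(seq_along(samples), function(i)
    seg_metrics(pr$fine_mask[[i]], samples[[i]]$lesion_mask))
  pos_score <- 1 - pr$scores[, 1L]
  labels <- vapply(samples, function(s) as.integer(s$class_label > 0L),
                   integer(1))
  list(summary = aggregate_metrics(per, pos_score, labels, threshold),
       per_image = per, scores = pos_score, labels = labels)
}

#' @export
print.ctgnet <- function(x, ...) {
  cat("Cross-task guided network fit\n")
  cat(sprintf("  image %dx%d, %d classes, %s encoder, D=%d\n",
              x$config$image_size, x$config$image_size,
              x$config$num_classes, x$config$backbone$kind,
              x$config$backbone$channels))
  cat(sprintf("  epochs run: %d (best validation epoch: %d)\n",
              x$epochs_run, x$best_epoch))
  last <- x$log[nrow(x$log), ]
  cat(sprintf("  final losses: cls %.4f, coarse %.4f, fine %.4f\n",
              last$l_cls, last$l_cseg, last$l_fseg))
  invisible(x)
}

#' @export
summary.ctgnet <- function(object, ...) {
  npar <- sum(vapply(object$params, length, integer(1)))
  res <- list(config = object$config, n_params = npar,
              epochs_run = object$epochs_run,
              best_epoch = object$best_epoch,
              log = object$log)
  class(res) <- "summary.ctgnet"
  res
}

#' @export
print.summary.ctgnet <- function(x, ...) {
  cat(sprintf("ctgnet model, %d parameters\n", x$n_params))
  cat(sprintf("  modules: LAM %s, CSM %s, AKGM %s\n",
              x$config$lam$use_masks, x$config$fine$use_csm,
              x$config$fine$use_akgm))
  cat(sprintf("  epochs: %d, best %d\n", x$epochs_run, x$best_epoch))
  print(utils::tail(x$log, 3L), row.names = FALSE)
  invisible(x)
}

#' @export
coef.ctgnet <- function(object, ...) object$params

#' @export
plot.ctgnet <- function(x, ...) {
  lg <- x$log
  op <- graphics::par(mfrow = c(1, 2), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  ylim <- range(c(lg$l_cls, lg$l_cseg, lg$l_fseg,
                  if ("val_l_total" %in% names(lg)) lg$val_l_total),
                na.rm = TRUE)
  plot(lg$epoch, lg$l_cls, type = "l", col = "firebrick", ylim = ylim,
       xlab = "epoch", ylab = "loss", main = "task losses")
  graphics::lines(lg$epoch, lg$l_cseg, col = "steelblue")
  graphics::lines(lg$epoch, lg$l_fseg, col = "darkgreen")
  if ("val_l_total" %in% names(lg))
    graphics::lines(lg$epoch, lg$val_l_total, lty = 2)
  graphics::legend("topright", c("cls", "coarse", "fine", "val total"),
                   col = c("firebrick", "steelblue", "darkgreen", "black"),
                   lty = c(1, 1, 1, 2), cex = 0.8, bty = "n")
  plot(lg$epoch, lg$lambda1, type = "l", ylim = c(0, 2),
       xlab = "epoch", ylab = "task weight", main = "DWA weights")
  graphics::lines(lg$epoch, lg$lambda2, lty = 2)
  graphics::abline(h = 1, col = "grey")
  invisible(x)
}

#' @export
simulate.ctgnet <- function(object, nsim = 1, seed = NULL, ...) {
  pc <- object$phantom_config
  if (is.null(pc)) pc <- phantom_config(
    image_height = object$config$image_size,
    image_width = object$config$image_size,
    classes = if (object$config$num_classes == 3L) "threeclass" else "binary",
    seed = if (is.null(seed)) object$seed else seed)
  if (!is.null(seed)) pc$seed <- as.integer(seed)
  generate_dataset(pc, nsim)
}

#' @export
residuals.ctgnet <- function(object, newdata, ...) {
  pr <- predict(object, newdata, type = "fine")
  lapply(seq_along(newdata), function(i)
    newdata[[i]]$lesion_mask - pr$fine_prob[[i]])
}
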