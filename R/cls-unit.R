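#' Lesion attention module (LAM)
#'
#' Enhances the shared features with gland- and lesion-masked copies:
#' `F_ma = F' * M_m`, `F_la = F' * M_l` (single-channel soft masks
#' broadcast across all channels) and `F_LAM = F' + F_ma + F_la`. The
#' full-resolution soft masks are bilinearly resized to the feature grid
#' before the multiplication, preserving their probabilistic character.
#'
#' @param f a `"shared_features"` object.
#' @param m a `"coarse_mask_probs"` object (channels lesion, gland,
#'   background) at image resolution.
#' @return An object of class `"lam_features"` with `f_lam`, `f_ma`,
#'   `f_la` (D x H x W arrays satisfying `f_lam = f' + f_ma + f_la`).
#' @export
lam <- function(f, m) {
  stopifnot(inherits(f, "shared_features"), inherits(m, "coarse_mask_probs"))
  d <- dim(f$values)
  fp <- arr3_to_mat(f$values)
  mfeat <- mask_to_feature_res(arr3_to_mat(m$values),
                               m$image_size[1], m$image_size[2],
                               d[2], d[3])
  if (ncol(mfeat) != ncol(fp))
    stop("internal contract violation: mask/feature shape mismatch")
  D <- d[1]
  f_la <- fp * rep(mfeat[1, ], each = D)
  f_ma <- fp * rep(mfeat[2, ], each = D)
  structure(list(f_lam = mat_to_arr3(fp + f_ma + f_la, d[2], d[3]),
                 f_ma = mat_to_arr3(f_ma, d[2], d[3]),
                 f_la = mat_to_arr3(f_la, d[2], d[3])),
            class = "lam_features")
}

#' Classify an image from lesion-attention features
#'
#' Global average pooling of `F_LAM` gives a length-D vector; an affine
#' map produces the per-class global feature matrix `G_global` (D1 x C),
#' and a second affine map (a shared weight vector applied to each class
#' column) produces the C logits whose softmax is the prediction score
#' vector `H_score`.
#'
#' @param lf a `"lam_features"` object from [lam()].
#' @param params parameters from [ctg_init()]; D1 and C are taken from
#'   their shapes.
#' @return An object of class `"class_prediction"` with `g_global`
#'   (D1 x C), `h_score` (length-C simplex vector) and `logits`.
#' @export
classify <- function(lf, params) {
  stopifnot(inherits(lf, "lam_features"))
  D1 <- length(params$cls_u)
  C <- length(params$cls_b)
  flam <- arr3_to_mat(lf$f_lam)
  pooled <- rowMeans(flam)
  Z <- as.vector(params$cls_W1 %*% pooled + params$cls_b1)
  G <- matrix(Z, D1, C)
  logits <- as.vector(crossprod(G, params$cls_u)) + params$cls_b
  h <- exp(logits - max(logits))
  h <- h / sum(h)
  structure(list(g_global = G, h_score = h, logits = logits),
            class = "class_prediction")
}

#' @export
print.class_prediction <- function(x, ...) {
  cat("class_prediction: scores",
      paste(sprintf("%.3f", x$h_score), collapse = " "), "\n")
  invisible(x)
}
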