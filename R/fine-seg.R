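#' Category selection module (CSM)
#'
#' Builds class-aware spatial features from the classification output:
#' the per-class global features `G_global` are transformed by a 1x1
#' (affine) map, each class column is reweighted by its prediction score
#' `h_c`, the shared features are projected to C channels by a 1x1
#' convolution, and the matrix product of the two gives a D1-channel
#' weighted feature map over all classes.
#'
#' @param f a `"shared_features"` object.
#' @param pred a `"class_prediction"` from [classify()].
#' @param params parameters from [ctg_init()].
#' @return D1 x H x W array of category attention features.
#' @export
csm <- function(f, pred, params) {
  stopifnot(inherits(f, "shared_features"),
            inherits(pred, "class_prediction"))
  C <- length(params$csm_P_b)
  if (ncol(pred$g_global) != C || length(pred$h_score) != C)
    stop("class count mismatch between prediction (",
         length(pred$h_score), ") and parameters (", C, ")")
  d <- dim(f$values)
  fp <- arr3_to_mat(f$values)
  Wg <- params$csm_A %*% pred$g_global + params$csm_a
  Wh <- Wg * rep(pred$h_score, each = nrow(Wg))
  P <- params$csm_P_W %*% fp + params$csm_P_b
  mat_to_arr3(Wh %*% P, d[2], d[3])
}

#' Anatomical knowledge guidance module (AKGM)
#'
#' Gland-masked self-attention over the shared features: Q, K (reduced
#' depth D' = max(1, D/8)) and V are 1x1 convolutions of F'; Q and K are
#' gated by the soft gland mask, the row-softmax of `t(Q') K'` gives the
#' N x N similarity matrix S (each output position a convex combination
#' over key positions), and the output is `alpha * V t(S) + F'` with the
#' learnable scalar `alpha` initialised to zero, so the module is exactly
#' the identity before training.
#'
#' @param f a `"shared_features"` object.
#' @param m_gland soft gland mask, either at image resolution (resized
#'   internally) or already on the feature grid.
#' @param params parameters from [ctg_init()].
#' @return D x H x W array of gland-constrained self-attention features.
#' @export
akgm <- function(f, m_gland, params) {
  stopifnot(inherits(f, "shared_features"), is.matrix(m_gland))
  d <- dim(f$values)
  if (!all(dim(m_gland) == d[2:3])) {
    m_gland <- matrix(mask_to_feature_res(
      matrix(as.numeric(m_gland), 1L, length(m_gland)),
      nrow(m_gland), ncol(m_gland), d[2], d[3]), d[2], d[3])
  }
  fp <- arr3_to_mat(f$values)
  out <- akgm_fw(params, fp, as.numeric(m_gland), d[2] * d[3], 1L)
  mat_to_arr3(out$out, d[2], d[3])
}

#' Fuse fine-segmentation features
#'
#' Channel concatenation of the category-selection and anatomically
#' guided attention features; either may be omitted for ablation runs.
#'
#' @param f_csm D1 x H x W array from [csm()] or `NULL`.
#' @param f_akgm D x H x W array from [akgm()] or `NULL`.
#' @param image_size `c(H, W)` of the original image.
#' @return Object of class `"fine_features"` with `f_fine` the channel
#'   concatenation `[f_csm; f_akgm]`.
#' @export
fine_features <- function(f_csm = NULL, f_akgm = NULL, image_size) {
  if (is.null(f_csm) && is.null(f_akgm))
    stop("at least one of f_csm, f_akgm is required")
  parts <- Filter(Negate(is.null), list(f_csm, f_akgm))
  sp <- dim(parts[[1]])[2:3]
  mats <- lapply(parts, arr3_to_mat)
  structure(list(f_csm = f_csm, f_akgm = f_akgm,
                 f_fine = mat_to_arr3(do.call(rbind, mats), sp[1], sp[2]),
                 image_size = image_size),
            class = "fine_features")
}

#' Fine lesion segmentation
#'
#' Decodes the fused fine features to a full-resolution two-channel
#' per-pixel probability map (channel 1 = lesion) with the same
#' bilinear-upsample + two-convolution decoder pattern as the coarse
#' unit, ending in a 2-channel convolution and per-pixel softmax.
#'
#' @param ff a `"fine_features"` object.
#' @param params parameters from [ctg_init()].
#' @return 2 x H x W array of probabilities summing to 1 per pixel.
#' @export
fine_segment <- function(ff, params) {
  stopifnot(inherits(ff, "fine_features"))
  d <- dim(ff$f_fine)
  fm <- arr3_to_mat(ff$f_fine)
  fi <- decoder_fw(params, "fdec", params$fhead_W, params$fhead_b,
                   fm, d[2], d[3], 1L, ff$image_size[1], ff$image_size[2])
  mat_to_arr3(softmax_cols(fi$logits_img), ff$image_size[1],
              ff$image_size[2])
}
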