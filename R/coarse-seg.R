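#' Coarse three-tissue segmentation
#'
#' Decodes shared features into per-pixel probabilities for the three
#' coarse tissue classes at full image resolution: four x2 bilinear
#' upsampling stages, each followed by two 3x3 convolutions, then a
#' 3-channel 1x1 convolution; the logits are bilinearly resized to the
#' exact image size and passed through a per-pixel softmax. Channel order
#' is (lesion, gland, background).
#'
#' @param f a `"shared_features"` object from [extract_shared_features()].
#' @param params parameters from [ctg_init()].
#' @return An object of class `"coarse_mask_probs"` with `values`
#'   (3 x H x W array of probabilities summing to 1 per pixel).
#' @export
coarse_segment <- function(f, params) {
  stopifnot(inherits(f, "shared_features"))
  d <- dim(f$values)
  fp <- arr3_to_mat(f$values)
  co <- decoder_fw(params, "cdec", params$chead_W, params$chead_b,
                   fp, d[2], d[3], 1L, f$image_size[1], f$image_size[2])
  probs <- softmax_cols(co$logits_img)
  structure(list(values = mat_to_arr3(probs, f$image_size[1],
                                      f$image_size[2]),
                 image_size = f$image_size),
            class = "coarse_mask_probs")
}

#' Hard label map from soft coarse masks
#'
#' Per-pixel argmax with ties broken toward the lower channel index
#' (lesion before gland before background). Returns labels in the
#' phantom convention: 0 = background, 1 = gland, 2 = lesion.
#'
#' @param m a `"coarse_mask_probs"` object (or a 3 x H x W array).
#' @return HxW integer label matrix.
#' @export
hard_mask <- function(m) {
  v <- if (inherits(m, "coarse_mask_probs")) m$values else m
  stopifnot(length(dim(v)) == 3L, dim(v)[1] == 3L)
  H <- dim(v)[2]; W <- dim(v)[3]
  chan <- max.col(t(arr3_to_mat(v)), ties.method = "first")
  matrix(c(2L, 1L, 0L)[chan], H, W)
}

#' @export
print.coarse_mask_probs <- function(x, ...) {
  lab <- hard_mask(x)
  cat(sprintf("coarse_mask_probs %dx%d: %d lesion px, %d gland px\n",
              dim(x$values)[2], dim(x$values)[3],
              sum(lab == 2L), sum(lab == 1L)))
  invisible(x)
}

# resize image-resolution soft masks (channels x Himg x Wimg) to the
# feature grid of f; used by the attention modules
mask_to_feature_res <- function(m_img, Himg, Wimg, Hf, Wf) {
  cpp_bilinear_fw(m_img, as.integer(Himg), as.integer(Wimg), 1L,
                  as.integer(Hf), as.integer(Wf))
}
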