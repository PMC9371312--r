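mat_to_arr3 <- function(m, H, W) array(m, c(nrow(m), H, W))
arr3_to_mat <- function(a) matrix(a, dim(a)[1], dim(a)[2] * dim(a)[3])

#' Extract shared features from an image
#'
#' Runs the convolutional encoder followed by atrous spatial pyramid
#' pooling (one dilated 3x3 branch per configured rate plus a 1x1 branch,
#' fused by channel concatenation and a 1x1 projection) to produce the
#' shared representation F' consumed by all three task units.
#'
#' @param image HxW numeric matrix with intensities in \[0, 1\].
#' @param cfg a [ctg_config()].
#' @param params parameters from [ctg_init()].
#' @return An object of class `"shared_features"`: `values` (D x H/8 x W/8
#'   array), `stride`, and `image_size = c(H, W)`.
#' @export
#' @examples
#' cfg <- ctg_config(desk_profile = TRUE)
#' p <- ctg_init(cfg, seed = 1)
#' img <- matrix(runif(64 * 64), 64, 64)
#' f <- extract_shared_features(img, cfg, p)
#' dim(f$values)
extract_shared_features <- function(image, cfg, params) {
  stopifnot(is.matrix(image))
  if (min(image) < 0 || max(image) > 1)
    stop("image intensities must lie in [0, 1]")
  H <- nrow(image); W <- ncol(image)
  stride <- cfg$backbone$stride
  if (H %% stride != 0L || W %% stride != 0L || H < 4L * stride)
    stop("image size must be a multiple of the stride (", stride, ")")
  X <- matrix(as.numeric(image), 1L, H * W)
  ea <- enc_aspp_fw(params, cfg, X, H, W, 1L)
  structure(list(values = mat_to_arr3(ea$fprime, ea$Hf, ea$Wf),
                 stride = stride, image_size = c(H, W)),
            class = "shared_features")
}

#' @export
print.shared_features <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("shared_features: %d channels x %dx%d (stride %d)\n",
              d[1], d[2], d[3], x$stride))
  invisible(x)
}
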