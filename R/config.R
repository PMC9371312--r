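#' Model and training configuration
#'
#' Builds the nested configuration list consumed by [ctg_init()],
#' [ctgnet_fit()] and the standalone unit operations. Defaults follow the
#' published training recipe (Adam with learning rate 1e-4, beta1 0.9,
#' beta2 0.99, eps 1e-8, up to 100 epochs, batch size 16, early-stopping
#' patience 10). The desk profile shrinks the network and schedule to
#' sizes a CPU can train in minutes: 64x64 inputs, a narrow 4-stage
#' encoder, 20 epochs, batch 8, and Adam at 1e-3 (a from-scratch tiny
#' network trained for a few hundred steps wants a larger step size than
#' a fine-tuned VGG16).
#'
#' @param desk_profile logical; use the reduced desk-scale profile.
#' @param image_size square input size in pixels; must be divisible by the
#'   backbone stride (8).
#' @param num_classes number of image classes C (2 = normal/lesion,
#'   3 = normal/benign/malignant).
#' @param ... named overrides for any nested entry, e.g.
#'   `backbone = list(channels = 64)`, `train = list(max_epochs = 5)`,
#'   `fine = list(use_csm = FALSE)`.
#'
#' @return A list of class `"ctg_config"` with entries `backbone`
#'   (`kind`, `base`, `channels`, `aspp_rates`, `stride`, `pretrained`),
#'   `cls` (`d1`), `lam` (`use_masks`), `fine` (`use_csm`, `use_akgm`),
#'   and `train` (`learning_rate`, `adam_beta1`, `adam_beta2`, `adam_eps`,
#'   `max_epochs`, `batch_size`, `patience`, `dwa_temperature`, `seed`).
#' @export
#' @examples
#' cfg <- ctg_config(desk_profile = TRUE)
#' cfg$backbone$channels
ctg_config <- function(desk_profile = FALSE,
                       image_size = if (desk_profile) 64L else 256L,
                       num_classes = 2L, ...) {
  cfg <- list(
    image_size = as.integer(image_size),
    num_classes = as.integer(num_classes),
    desk_profile = isTRUE(desk_profile),
    backbone = list(
      kind = "lightweight",
      base = if (desk_profile) 8L else 16L,
      channels = if (desk_profile) 32L else 64L,
      aspp_rates = c(1L, 2L, 4L),
      stride = 8L,
      pretrained = FALSE),
    cls = list(d1 = if (desk_profile) 16L else 32L),
    lam = list(use_masks = TRUE),
    fine = list(use_csm = TRUE, use_akgm = TRUE),
    train = list(
      learning_rate = if (desk_profile) 3e-3 else 1e-4,
      adam_beta1 = 0.9, adam_beta2 = 0.99, adam_eps = 1e-8,
      max_epochs = if (desk_profile) 20L else 100L,
      batch_size = if (desk_profile) 8L else 16L,
      patience = 10L,
      dwa_temperature = 2,
      seed = 1L)
  )
  dots <- list(...)
  for (nm in names(dots)) {
    if (is.list(dots[[nm]]) && is.list(cfg[[nm]])) {
      cfg[[nm]][names(dots[[nm]])] <- dots[[nm]]
    } else {
      cfg[[nm]] <- dots[[nm]]
    }
  }
  # a shortened schedule implies a shortened patience
  cfg$train$patience <- min(cfg$train$patience, cfg$train$max_epochs)
  validate_ctg_config(cfg)
  structure(cfg, class = "ctg_config")
}

validate_ctg_config <- function(cfg) {
  bb <- cfg$backbone
  if (!bb$kind %in% c("lightweight", "vgg16"))
    stop("backbone kind must be 'lightweight' or 'vgg16'")
  if (isTRUE(bb$pretrained))
    stop("pretrained weights are not bundled with this package; ",
         "set backbone$pretrained = FALSE")
  if (length(bb$aspp_rates) < 1L || any(bb$aspp_rates < 1L))
    stop("aspp_rates must be a non-empty set of dilation rates >= 1")
  if (bb$stride != 8L)
    stop("the provided encoders produce stride-8 features")
  if (cfg$image_size %% bb$stride != 0L || cfg$image_size < 4L * bb$stride)
    stop("image_size must be a multiple of the stride and at least 4x it")
  if (bb$channels < cfg$num_classes)
    stop("feature depth must be at least the number of classes")
  tr <- cfg$train
  if (tr$patience > tr$max_epochs) stop("patience must not exceed max_epochs")
  if (tr$batch_size < 1L) stop("batch_size must be >= 1")
  invisible(cfg)
}

#' Initialise network parameters
#'
#' He-normal initialisation for all convolutional and affine weights, zero
#' biases, and the self-attention residual scale `alpha` set exactly to
#' zero so the gland-guided attention starts as the identity on the shared
#' features.
#'
#' @param cfg a [ctg_config()] object.
#' @param seed integer seed; the returned parameters are a deterministic
#'   function of `(cfg, seed)`.
#' @return Named list of parameter matrices/vectors.
#' @export
ctg_init <- function(cfg, seed = cfg$train$seed) {
  validate_ctg_config(cfg)
  ctg_init_params(cfg, seed)
}
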