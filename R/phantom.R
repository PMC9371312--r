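# Synthetic breast-ultrasound phantoms: a bright skin/fat band on top, a
# mid-grey mammary-gland band, and a darker muscle region with periodic
# bright rib-like blobs. Lesions are hypoechoic (darker) regions placed
# entirely inside the gland band: benign lesions are smooth ellipses,
# malignant ones spiculated star polygons. Smoothing is followed by
# multiplicative unit-mean speckle, so expected layer contrast is
# preserved.

#' Phantom generator configuration
#'
#' @param image_height,image_width image size in pixels.
#' @param skin_band_fraction fraction of the height occupied by the
#'   skin/fat band, in \[0.05, 0.25\].
#' @param gland_band_fraction fraction occupied by the mammary-gland band,
#'   in \[0.2, 0.5\]; lesions occur only inside this band.
#' @param lesion_probability probability that an image contains a lesion.
#' @param malignant_fraction probability that a lesion is malignant
#'   (spiculated) rather than benign (elliptical).
#' @param lesion_radius_range `(min, max)` lesion radius in pixels; the
#'   radius is the geometric-mean semi-axis, so the lesion area is close
#'   to `pi * r^2` regardless of eccentricity.
#' @param speckle_strength standard deviation of the multiplicative
#'   unit-mean Gamma speckle; 0 disables speckle.
#' @param contrast_lesion intensity offset added inside the lesion, in
#'   \[-1, 0); hypoechoic lesions are darker than the gland.
#' @param blur_sigma Gaussian smoothing sigma (pixels) applied before
#'   speckle.
#' @param classes `"binary"` (normal vs lesion, the default) or
#'   `"threeclass"` (normal / benign / malignant).
#' @param seed integer; together with the sample index it fully determines
#'   each generated sample.
#' @return A list of class `"phantom_config"`.
#' @export
#' @examples
#' cfg <- phantom_config(seed = 7)
#' s <- generate_phantom(cfg, index = 0)
#' table(s$coarse_mask)
phantom_config <- function(image_height = 64L, image_width = 64L,
                           skin_band_fraction = 0.12,
                           gland_band_fraction = 0.35,
                           lesion_probability = 0.5,
                           malignant_fraction = 0.5,
                           lesion_radius_range = c(5, 10),
                           speckle_strength = 0.15,
                           contrast_lesion = -0.25,
                           blur_sigma = 1.0,
                           classes = c("binary", "threeclass"),
                           seed = 1L) {
  cfg <- list(image_height = as.integer(image_height),
              image_width = as.integer(image_width),
              skin_band_fraction = skin_band_fraction,
              gland_band_fraction = gland_band_fraction,
              lesion_probability = lesion_probability,
              malignant_fraction = malignant_fraction,
              lesion_radius_range = as.numeric(lesion_radius_range),
              speckle_strength = speckle_strength,
              contrast_lesion = contrast_lesion,
              blur_sigma = blur_sigma,
              classes = match.arg(classes),
              seed = as.integer(seed))
  validate_phantom_config(cfg)
  structure(cfg, class = "phantom_config")
}

validate_phantom_config <- function(cfg) {
  err <- function(...) stop("invalid phantom configuration: ", ...,
                            call. = FALSE)
  if (cfg$image_height < 16L || cfg$image_width < 16L)
    err("image must be at least 16x16")
  if (cfg$skin_band_fraction < 0.05 || cfg$skin_band_fraction > 0.25)
    err("skin_band_fraction must lie in [0.05, 0.25]")
  if (cfg$gland_band_fraction < 0.2 || cfg$gland_band_fraction > 0.5)
    err("gland_band_fraction must lie in [0.2, 0.5]")
  if (cfg$skin_band_fraction + cfg$gland_band_fraction >= 1)
    err("skin and gland band fractions must sum to less than 1")
  if (cfg$lesion_probability < 0 || cfg$lesion_probability > 1)
    err("lesion_probability must lie in [0, 1]")
  if (cfg$malignant_fraction < 0 || cfg$malignant_fraction > 1)
    err("malignant_fraction must lie in [0, 1]")
  rr <- cfg$lesion_radius_range
  if (length(rr) != 2L || rr[1] <= 0 || rr[2] < rr[1])
    err("lesion_radius_range must be (min, max) with 0 < min <= max")
  gland_px <- round(cfg$gland_band_fraction * cfg$image_height)
  if (rr[2] >= gland_px)
    err("max lesion radius must be smaller than the gland band height (",
        gland_px, " px)")
  if (cfg$speckle_strength < 0) err("speckle_strength must be >= 0")
  if (cfg$contrast_lesion < -1 || cfg$contrast_lesion >= 0)
    err("contrast_lesion must lie in [-1, 0)")
  invisible(cfg)
}

#' Generate one synthetic ultrasound phantom
#'
#' Deterministic in `(cfg$seed, index)`: calling twice with the same
#' arguments returns bit-identical samples.
#'
#' @param cfg a [phantom_config()].
#' @param index non-negative integer sample index.
#' @return A list of class `"phantom_sample"` with `image` (HxW matrix in
#'   \[0,1\]), `coarse_mask` (HxW integer, 0 = background, 1 = gland,
#'   2 = lesion), `lesion_mask` (HxW integer 0/1), `class_label` (0 =
#'   normal; 1 = lesion in binary mode; 1 = benign, 2 = malignant in
#'   three-class mode), `seed`, and `metadata` (including the pre-speckle
#'   `clean` image used by contrast checks).
#' @export
generate_phantom <- function(cfg, index) {
  validate_phantom_config(cfg)
  stopifnot(length(index) == 1L, index >= 0)
  sample_seed <- (cfg$seed %% 100003L) * 20011L + as.integer(index) + 1L
  old <- local_rng(sample_seed)
  on.exit(restore_rng(old))
  H <- cfg$image_height; W <- cfg$image_width
  skin_px <- max(1L, round(cfg$skin_band_fraction * H))
  gland_px <- round(cfg$gland_band_fraction * H)
  gland_rows <- (skin_px + 1L):(skin_px + gland_px)
  clean <- matrix(0.28 + stats::rnorm(1, 0, 0.02), H, W)
  clean[seq_len(skin_px), ] <- 0.70 + stats::rnorm(1, 0, 0.02)
  clean[gland_rows, ] <- 0.50 + stats::rnorm(1, 0, 0.02)
  # periodic bright rib-like blobs in the muscle region
  muscle_top <- skin_px + gland_px + 1L
  if (muscle_top + 4L < H) {
    rib_row <- round((muscle_top + H) / 2)
    rib_cols <- seq(round(W / 6), W, by = max(8L, round(W / 3)))
    rg <- expand.grid(r = seq_len(H), c = seq_len(W))
    for (rc in rib_cols) {
      bump <- 0.25 * exp(-((rg$r - rib_row)^2 + (rg$c - rc)^2) / (2 * 3^2))
      clean <- clean + matrix(bump, H, W)
    }
  }
  lesion_mask <- matrix(0L, H, W)
  malignant <- FALSE
  has_lesion <- stats::runif(1) < cfg$lesion_probability
  meta <- list()
  if (has_lesion) {
    malignant <- stats::runif(1) < cfg$malignant_fraction
    rr <- cfg$lesion_radius_range
    r <- stats::runif(1, rr[1], rr[2])
    max_ext <- floor((gland_px - 2) / 2)
    if (r > max_ext) r <- max_ext
    cgrid <- matrix(rep(seq_len(W), each = H), H, W)
    rgrid <- matrix(rep(seq_len(H), W), H, W)
    if (malignant) {
      m <- sample(7:12, 1L)
      amp <- stats::runif(1, 0.15, 0.30)
      amp2 <- stats::runif(1, 0, 0.05)
      if (r * (1 + amp + amp2) > max_ext)
        amp <- max(0, max_ext / r - 1 - amp2)
      phi0 <- stats::runif(1, 0, 2 * pi)
      psi <- stats::runif(1, 0, 2 * pi)
      ext <- r * (1 + amp + amp2)
      ctr <- lesion_centre(ext, gland_rows, W)
      dx <- cgrid - ctr[2]; dy <- rgrid - ctr[1]
      th <- atan2(dy, dx)
      rho <- r * (1 + amp * cos(m * th + phi0) + amp2 * cos(3 * th + psi))
      lesion_mask[sqrt(dx^2 + dy^2) <= rho] <- 1L
      meta$spikes <- m
    } else {
      ratio <- stats::runif(1, 0.6, 1.0)
      a <- r / sqrt(ratio)
      if (a > max_ext) a <- max_ext
      b <- r^2 / a
      phi <- stats::runif(1, 0, pi)
      ctr <- lesion_centre(a, gland_rows, W)
      dx <- cgrid - ctr[2]; dy <- rgrid - ctr[1]
      xr <- cos(phi) * dx + sin(phi) * dy
      yr <- -sin(phi) * dx + cos(phi) * dy
      lesion_mask[(xr / a)^2 + (yr / b)^2 <= 1] <- 1L
    }
    # lesions occur only in the mammary gland layer
    keep <- matrix(FALSE, H, W)
    keep[gland_rows, ] <- TRUE
    lesion_mask[!keep] <- 0L
    clean[lesion_mask == 1L] <- clean[lesion_mask == 1L] + cfg$contrast_lesion
    meta$radius <- r
  }
  clean <- pmin(pmax(clean, 0), 1)
  if (cfg$blur_sigma > 0)
    clean <- as.matrix(EBImage::gblur(clean, sigma = cfg$blur_sigma))
  clean <- pmin(pmax(clean, 0), 1)
  if (cfg$speckle_strength > 0) {
    sh <- 1 / cfg$speckle_strength^2
    image <- clean * matrix(stats::rgamma(H * W, shape = sh, rate = sh), H, W)
  } else {
    image <- clean
  }
  image <- pmin(pmax(image, 0), 1)
  coarse <- matrix(0L, H, W)
  coarse[gland_rows, ] <- 1L
  coarse[lesion_mask == 1L] <- 2L
  label <- if (!has_lesion) 0L
  else if (cfg$classes == "binary") 1L
  else if (malignant) 2L else 1L
  meta$clean <- clean
  meta$malignant <- malignant
  meta$gland_rows <- range(gland_rows)
  structure(list(image = image, coarse_mask = coarse,
                 lesion_mask = lesion_mask, class_label = label,
                 seed = sample_seed, index = as.integer(index),
                 metadata = meta),
            class = "phantom_sample")
}

lesion_centre <- function(ext, gland_rows, W) {
  lo <- min(gland_rows) + ext
  hi <- max(gland_rows) - ext
  if (hi < lo) { lo <- hi <- mean(gland_rows) }
  row <- stats::runif(1, lo, hi)
  col <- stats::runif(1, ext + 2, W - ext - 1)
  c(row, col)
}

#' Generate a list of phantoms
#'
#' @param cfg a [phantom_config()].
#' @param n number of samples.
#' @param start_index index of the first sample (default 0).
#' @return List of `"phantom_sample"` objects.
#' @export
generate_dataset <- function(cfg, n, start_index = 0L) {
  lapply(seq_len(n) - 1L + as.integer(start_index),
         function(i) generate_phantom(cfg, i))
}

#' Write a phantom dataset to disk
#'
#' Writes 8-bit grayscale image PNGs, coarse-mask label PNGs (raw values
#' 0/1/2), lesion-mask PNGs (0/255) and a `manifest.csv` with columns
#' `filename,class_label,seed`. The written files round-trip through
#' [read_dataset()] up to 8-bit quantisation of the image (masks and
#' labels are exact).
#'
#' @param samples list of `"phantom_sample"` objects.
#' @param out_dir output directory (created if needed).
#' @return Path of the manifest file, invisibly usable by [read_dataset()].
#' @export
write_dataset <- function(samples, out_dir) {
  if (!dir.exists(out_dir) &&
      !dir.create(out_dir, recursive = TRUE, showWarnings = FALSE))
    stop("cannot create output directory: ", out_dir)
  rows <- vector("list", length(samples))
  for (i in seq_along(samples)) {
    s <- samples[[i]]
    base <- sprintf("sample_%05d", s$index %||% (i - 1L))
    img_path <- file.path(out_dir, paste0(base, ".png"))
    png::writePNG(s$image, img_path)
    png::writePNG(s$coarse_mask / 255,
                  file.path(out_dir, paste0(base, "_coarse.png")))
    png::writePNG(s$lesion_mask * 1.0,
                  file.path(out_dir, paste0(base, "_lesion.png")))
    rows[[i]] <- data.frame(filename = paste0(base, ".png"),
                            class_label = s$class_label, seed = s$seed)
  }
  manifest <- file.path(out_dir, "manifest.csv")
  df <- if (length(rows)) do.call(rbind, rows)
  else data.frame(filename = character(), class_label = integer(),
                  seed = integer())
  utils::write.csv(df, manifest, row.names = FALSE)
  manifest
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read a phantom dataset from disk
#'
#' Inverse of [write_dataset()] up to 8-bit image quantisation.
#'
#' @param manifest path to a `manifest.csv` written by [write_dataset()].
#' @return List of `"phantom_sample"` objects.
#' @export
read_dataset <- function(manifest) {
  if (!file.exists(manifest)) stop("manifest not found: ", manifest)
  df <- utils::read.csv(manifest)
  need <- c("filename", "class_label", "seed")
  if (!all(need %in% names(df)))
    stop("malformed manifest, expected columns: ",
         paste(need, collapse = ", "))
  dir <- dirname(manifest)
  lapply(seq_len(nrow(df)), function(i) {
    base <- sub("\\.png$", "", df$filename[i])
    paths <- file.path(dir, paste0(base, c(".png", "_coarse.png",
                                           "_lesion.png")))
    for (pth in paths)
      if (!file.exists(pth)) stop("referenced file is missing: ", pth)
    img <- drop_alpha(png::readPNG(paths[1]))
    coarse <- round(255 * drop_alpha(png::readPNG(paths[2])))
    if (!all(coarse %in% 0:2))
      stop("coarse mask ", paths[2], " has values outside {0,1,2}")
    lesion <- round(drop_alpha(png::readPNG(paths[3])))
    if (!all(lesion %in% 0:1))
      stop("lesion mask ", paths[3], " has values outside {0,255}")
    if (!all(coarse[lesion == 1] == 2))
      stop("inconsistent masks for ", base,
           ": lesion pixels must be labelled 2 in the coarse mask")
    structure(list(image = img,
                   coarse_mask = matrix(as.integer(coarse), nrow(coarse)),
                   lesion_mask = matrix(as.integer(lesion), nrow(lesion)),
                   class_label = as.integer(df$class_label[i]),
                   seed = as.integer(df$seed[i]),
                   index = i - 1L,
                   metadata = list(source = paths[1])),
              class = "phantom_sample")
  })
}

drop_alpha <- function(x) {
  if (length(dim(x)) == 3L) x[, , 1L] else x
}

#' @export
print.phantom_sample <- function(x, ...) {
  cat(sprintf("phantom_sample %dx%d, class %d (%s), %d lesion px\n",
              nrow(x$image), ncol(x$image), x$class_label,
              c("normal", "lesion")[1L + (x$class_label > 0)],
              sum(x$lesion_mask)))
  invisible(x)
}
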