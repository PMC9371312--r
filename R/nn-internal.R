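# Internal tensor utilities. Feature maps are D x (H*W*B) matrices,
# column-major spatial layout (pixel n = r + (c-1)*H), images stacked
# along the column dimension. All forward functions return caches that
# their _bw counterparts consume; backprop is fully analytic and is
# validated against finite differences in the test suite.

conv3_fw <- function(x, H, W, B, Wm, b, dil = 1L) {
  out <- cpp_conv3_fw(x, Wm, b, as.integer(H), as.integer(W),
                      as.integer(B), as.integer(dil))
  list(out = out, x = x)
}

conv3_bw <- function(dout, cache, Wm, H, W, B, dil = 1L) {
  bw <- cpp_conv3_bw(dout, cache$x, Wm, as.integer(H), as.integer(W),
                     as.integer(B), as.integer(dil))
  list(dW = bw$dW, db = rowSums(dout), dx = bw$dx)
}

# instance normalisation: each channel standardised over the spatial
# positions of its own image, then an affine per-channel map. Used inside
# the decoder conv blocks: the soft Dice objective rewards ever more
# confident softmax outputs, and without a normalisation stage the decoder
# activations grow without bound until the per-pixel softmax saturates and
# gradients vanish. Batch-independent, so inference is deterministic.
instnorm_fw <- function(x, N, B, g, be, eps = 1e-5) {
  xhat <- x
  istd <- matrix(0, nrow(x), B)
  for (b in seq_len(B)) {
    cols <- (b - 1L) * N + seq_len(N)
    xb <- x[, cols, drop = FALSE]
    mu <- rowMeans(xb)
    v <- rowMeans(xb * xb) - mu * mu
    is <- 1 / sqrt(pmax(v, 0) + eps)
    xhat[, cols] <- (xb - mu) * is
    istd[, b] <- is
  }
  list(out = xhat * g + be, xhat = xhat, istd = istd)
}

instnorm_bw <- function(dy, cache, g, N, B) {
  xhat <- cache$xhat
  dg <- rowSums(dy * xhat)
  db <- rowSums(dy)
  dxhat <- dy * g
  dx <- dxhat
  for (b in seq_len(B)) {
    cols <- (b - 1L) * N + seq_len(N)
    dxb <- dxhat[, cols, drop = FALSE]
    xb <- xhat[, cols, drop = FALSE]
    dx[, cols] <- (dxb - rowMeans(dxb) - xb * rowMeans(dxb * xb)) *
      cache$istd[, b]
  }
  list(dx = dx, dg = dg, db = db)
}

relu_fw <- function(x) {
  mask <- x > 0
  list(out = x * mask, mask = mask)
}

relu_bw <- function(dout, mask) dout * mask

# softmax over rows (channels) of a C x N matrix, columnwise normalisation
softmax_cols <- function(z) {
  m <- do.call(pmax, lapply(seq_len(nrow(z)), function(i) z[i, ]))
  e <- exp(z - rep(m, each = nrow(z)))
  e / rep(colSums(e), each = nrow(z))
}

# given probs p (C x N) and upstream dL/dp, return dL/dlogits
softmax_cols_bw <- function(dp, p) {
  p * (dp - rep(colSums(dp * p), each = nrow(p)))
}

# row softmax of an N x N score matrix (each row a distribution over keys)
softmax_rows <- function(E) {
  m <- E[cbind(seq_len(nrow(E)), max.col(E, ties.method = "first"))]
  e <- exp(E - m)
  e / rowSums(e)
}

softmax_rows_bw <- function(dS, S) {
  S * (dS - rowSums(dS * S))
}

he_mat <- function(nout, nin) {
  matrix(stats::rnorm(nout * nin, sd = sqrt(2 / nin)), nout, nin)
}

# ---- architecture description ----------------------------------------------

encoder_spec <- function(cfg) {
  bb <- cfg$backbone
  if (bb$kind == "lightweight") {
    b <- as.integer(bb$base)
    list(widths = c(b, 2L * b, 4L * b, 4L * b),
         convs = c(1L, 1L, 1L, 1L),
         pool = c(TRUE, TRUE, TRUE, FALSE))
  } else if (bb$kind == "vgg16") {
    # first three VGG16 blocks (cut point at stride 8), random init
    list(widths = c(64L, 128L, 256L),
         convs = c(2L, 2L, 3L),
         pool = c(TRUE, TRUE, TRUE))
  } else {
    stop("unknown encoder kind: ", bb$kind)
  }
}

decoder_widths <- function(din) {
  pmax(4L, din %/% c(2L, 4L, 8L, 8L))
}

fine_input_depth <- function(cfg) {
  d <- 0L
  if (cfg$fine$use_csm) d <- d + as.integer(cfg$cls$d1)
  if (cfg$fine$use_akgm) d <- d + as.integer(cfg$backbone$channels)
  if (d == 0L) stop("at least one of use_csm/use_akgm must be TRUE")
  d
}

# ---- parameter initialisation ----------------------------------------------

ctg_init_params <- function(cfg, seed) {
  old <- local_rng(seed)
  on.exit(restore_rng(old))
  es <- encoder_spec(cfg)
  D <- as.integer(cfg$backbone$channels)
  D1 <- as.integer(cfg$cls$d1)
  C <- as.integer(cfg$num_classes)
  rates <- as.integer(cfg$backbone$aspp_rates)
  p <- list()
  din <- 1L
  for (s in seq_along(es$widths)) {
    for (j in seq_len(es$convs[s])) {
      w <- es$widths[s]
      p[[sprintf("enc_s%d_c%d_W", s, j)]] <- he_mat(w, din * 9L)
      p[[sprintf("enc_s%d_c%d_b", s, j)]] <- numeric(w)
      din <- w
    }
  }
  E <- din
  Db <- max(4L, D %/% 4L)
  p$aspp_b0_W <- he_mat(Db, E); p$aspp_b0_b <- numeric(Db)
  for (r in rates) {
    p[[sprintf("aspp_r%d_W", r)]] <- he_mat(Db, E * 9L)
    p[[sprintf("aspp_r%d_b", r)]] <- numeric(Db)
  }
  nbr <- 1L + length(rates)
  p$aspp_p_W <- he_mat(D, nbr * Db); p$aspp_p_b <- numeric(D)
  # coarse decoder: four x2 upsampling stages, two convs each
  cw <- decoder_widths(D)
  din2 <- D
  for (i in 1:4) {
    p[[sprintf("cdec%d_a_W", i)]] <- he_mat(cw[i], din2 * 9L)
    p[[sprintf("cdec%d_a_b", i)]] <- numeric(cw[i])
    p[[sprintf("cdec%d_a_g", i)]] <- rep(1, cw[i])
    p[[sprintf("cdec%d_a_be", i)]] <- numeric(cw[i])
    p[[sprintf("cdec%d_b_W", i)]] <- he_mat(cw[i], cw[i] * 9L)
    p[[sprintf("cdec%d_b_b", i)]] <- numeric(cw[i])
    p[[sprintf("cdec%d_b_g", i)]] <- rep(1, cw[i])
    p[[sprintf("cdec%d_b_be", i)]] <- numeric(cw[i])
    din2 <- cw[i]
  }
  p$chead_W <- he_mat(3L, cw[4]); p$chead_b <- numeric(3L)
  # classification head
  p$cls_W1 <- he_mat(D1 * C, D); p$cls_b1 <- numeric(D1 * C)
  p$cls_u <- stats::rnorm(D1, sd = sqrt(2 / D1)); p$cls_b <- numeric(C)
  # CSM
  p$csm_A <- he_mat(D1, D1); p$csm_a <- numeric(D1)
  p$csm_P_W <- he_mat(C, D); p$csm_P_b <- numeric(C)
  # AKGM (no biases on q/k/v, standard non-local form; alpha starts at 0)
  Dp <- max(1L, D %/% 8L)
  p$akgm_Wq <- he_mat(Dp, D)
  p$akgm_Wk <- he_mat(Dp, D)
  p$akgm_Wv <- he_mat(D, D)
  p$akgm_alpha <- 0
  # fine decoder
  fin <- fine_input_depth(cfg)
  fw <- decoder_widths(fin)
  din3 <- fin
  for (i in 1:4) {
    p[[sprintf("fdec%d_a_W", i)]] <- he_mat(fw[i], din3 * 9L)
    p[[sprintf("fdec%d_a_b", i)]] <- numeric(fw[i])
    p[[sprintf("fdec%d_a_g", i)]] <- rep(1, fw[i])
    p[[sprintf("fdec%d_a_be", i)]] <- numeric(fw[i])
    p[[sprintf("fdec%d_b_W", i)]] <- he_mat(fw[i], fw[i] * 9L)
    p[[sprintf("fdec%d_b_b", i)]] <- numeric(fw[i])
    p[[sprintf("fdec%d_b_g", i)]] <- rep(1, fw[i])
    p[[sprintf("fdec%d_b_be", i)]] <- numeric(fw[i])
    din3 <- fw[i]
  }
  p$fhead_W <- he_mat(2L, fw[4]); p$fhead_b <- numeric(2L)
  p
}

# save/restore the global RNG so seeded internals do not disturb user code
local_rng <- function(seed) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(as.integer(seed))
  old
}

restore_rng <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
  invisible(NULL)
}

# ---- encoder + ASPP ---------------------------------------------------------

enc_aspp_fw <- function(p, cfg, X, H, W, B) {
  es <- encoder_spec(cfg)
  rates <- as.integer(cfg$backbone$aspp_rates)
  cache <- list(stages = list())
  x <- X; h <- H; w <- W
  for (s in seq_along(es$widths)) {
    st <- list(convs = list(), h = h, w = w)
    for (j in seq_len(es$convs[s])) {
      cv <- conv3_fw(x, h, w, B, p[[sprintf("enc_s%d_c%d_W", s, j)]],
                     p[[sprintf("enc_s%d_c%d_b", s, j)]])
      rl <- relu_fw(cv$out)
      st$convs[[j]] <- list(x = cv$x, mask = rl$mask)
      x <- rl$out
    }
    if (es$pool[s]) {
      mp <- cpp_maxpool_fw(x, as.integer(h), as.integer(w), as.integer(B))
      st$pool_idx <- mp$idx
      st$ncol_in <- ncol(x)
      x <- mp$out
      h <- h %/% 2L; w <- w %/% 2L
    }
    cache$stages[[s]] <- st
  }
  cache$enc_out <- x; cache$Hf <- h; cache$Wf <- w
  # ASPP: 1x1 branch + one dilated 3x3 branch per rate, concat, 1x1 projection
  b0 <- relu_fw(p$aspp_b0_W %*% x + p$aspp_b0_b)
  branches <- list(b0$out)
  cache$aspp_b0_mask <- b0$mask
  cache$aspp_r <- list()
  for (r in rates) {
    cv <- conv3_fw(x, h, w, B, p[[sprintf("aspp_r%d_W", r)]],
                   p[[sprintf("aspp_r%d_b", r)]], dil = r)
    rl <- relu_fw(cv$out)
    cache$aspp_r[[as.character(r)]] <- list(x = cv$x, mask = rl$mask)
    branches[[length(branches) + 1L]] <- rl$out
  }
  cat_x <- do.call(rbind, branches)
  cache$aspp_cat <- cat_x
  pj <- relu_fw(p$aspp_p_W %*% cat_x + p$aspp_p_b)
  cache$aspp_p_mask <- pj$mask
  list(fprime = pj$out, Hf = h, Wf = w, cache = cache)
}

enc_aspp_bw <- function(p, cfg, cache, dfp, B) {
  es <- encoder_spec(cfg)
  rates <- as.integer(cfg$backbone$aspp_rates)
  g <- list()
  h <- cache$Hf; w <- cache$Wf
  dz <- relu_bw(dfp, cache$aspp_p_mask)
  g$aspp_p_W <- tcrossprod(dz, cache$aspp_cat)
  g$aspp_p_b <- rowSums(dz)
  dcat <- crossprod(p$aspp_p_W, dz)
  Db <- nrow(p$aspp_b0_W)
  dx <- matrix(0, nrow(cache$enc_out), ncol(cache$enc_out))
  d0 <- relu_bw(dcat[seq_len(Db), , drop = FALSE], cache$aspp_b0_mask)
  g$aspp_b0_W <- tcrossprod(d0, cache$enc_out)
  g$aspp_b0_b <- rowSums(d0)
  dx <- dx + crossprod(p$aspp_b0_W, d0)
  off <- Db
  for (r in rates) {
    dr <- relu_bw(dcat[off + seq_len(Db), , drop = FALSE],
                  cache$aspp_r[[as.character(r)]]$mask)
    bw <- conv3_bw(dr, cache$aspp_r[[as.character(r)]], p[[sprintf("aspp_r%d_W", r)]],
                   h, w, B, dil = r)
    g[[sprintf("aspp_r%d_W", r)]] <- bw$dW
    g[[sprintf("aspp_r%d_b", r)]] <- bw$db
    dx <- dx + bw$dx
    off <- off + Db
  }
  # back through encoder stages in reverse
  for (s in rev(seq_along(es$widths))) {
    st <- cache$stages[[s]]
    if (es$pool[s]) {
      dx <- cpp_maxpool_bw(dx, st$pool_idx, as.integer(st$ncol_in))
      h <- st$h; w <- st$w
    } else {
      h <- st$h; w <- st$w
    }
    for (j in rev(seq_len(es$convs[s]))) {
      nm <- sprintf("enc_s%d_c%d", s, j)
      dz <- relu_bw(dx, st$convs[[j]]$mask)
      bw <- conv3_bw(dz, st$convs[[j]], p[[paste0(nm, "_W")]], h, w, B)
      g[[paste0(nm, "_W")]] <- bw$dW
      g[[paste0(nm, "_b")]] <- bw$db
      dx <- bw$dx
    }
  }
  list(grads = g, dX = dx)
}

# ---- shared decoder pattern: four x2 bilinear upsamplings, two convs each ---

decoder_fw <- function(p, prefix, head_W, head_b, x, Hf, Wf, B, Himg, Wimg) {
  cache <- list(stages = list())
  h <- Hf; w <- Wf
  for (i in 1:4) {
    st <- list(h_in = h, w_in = w, x_cols = ncol(x))
    x <- cpp_bilinear_fw(x, as.integer(h), as.integer(w), as.integer(B),
                         as.integer(2L * h), as.integer(2L * w))
    h <- 2L * h; w <- 2L * w
    cva <- conv3_fw(x, h, w, B, p[[sprintf("%s%d_a_W", prefix, i)]],
                    p[[sprintf("%s%d_a_b", prefix, i)]])
    nna <- instnorm_fw(cva$out, h * w, B, p[[sprintf("%s%d_a_g", prefix, i)]],
                       p[[sprintf("%s%d_a_be", prefix, i)]])
    rla <- relu_fw(nna$out)
    cvb <- conv3_fw(rla$out, h, w, B, p[[sprintf("%s%d_b_W", prefix, i)]],
                    p[[sprintf("%s%d_b_b", prefix, i)]])
    nnb <- instnorm_fw(cvb$out, h * w, B, p[[sprintf("%s%d_b_g", prefix, i)]],
                       p[[sprintf("%s%d_b_be", prefix, i)]])
    rlb <- relu_fw(nnb$out)
    st$a <- list(x = cva$x, mask = rla$mask,
                 nrm = nna[c("xhat", "istd")])
    st$b <- list(x = cvb$x, mask = rlb$mask,
                 nrm = nnb[c("xhat", "istd")])
    cache$stages[[i]] <- st
    x <- rlb$out
  }
  cache$Hd <- h; cache$Wd <- w
  cache$last <- x
  logits_dec <- head_W %*% x + head_b
  logits_img <- cpp_bilinear_fw(logits_dec, as.integer(h), as.integer(w),
                                as.integer(B), as.integer(Himg), as.integer(Wimg))
  cache$logits_dec_cols <- NULL
  list(logits_img = logits_img, cache = cache)
}

decoder_bw <- function(p, prefix, head_W, dlogits_img, cache, B, Himg, Wimg) {
  g <- list()
  h <- cache$Hd; w <- cache$Wd
  dld <- cpp_bilinear_bw(dlogits_img, as.integer(h), as.integer(w),
                         as.integer(B), as.integer(Himg), as.integer(Wimg))
  g$head_W <- tcrossprod(dld, cache$last)
  g$head_b <- rowSums(dld)
  dx <- crossprod(head_W, dld)
  for (i in 4:1) {
    st <- cache$stages[[i]]
    dz <- relu_bw(dx, st$b$mask)
    nb <- instnorm_bw(dz, st$b$nrm, p[[sprintf("%s%d_b_g", prefix, i)]],
                      h * w, B)
    g[[sprintf("%s%d_b_g", prefix, i)]] <- nb$dg
    g[[sprintf("%s%d_b_be", prefix, i)]] <- nb$db
    bwb <- conv3_bw(nb$dx, st$b, p[[sprintf("%s%d_b_W", prefix, i)]], h, w, B)
    g[[sprintf("%s%d_b_W", prefix, i)]] <- bwb$dW
    g[[sprintf("%s%d_b_b", prefix, i)]] <- bwb$db
    dz <- relu_bw(bwb$dx, st$a$mask)
    na <- instnorm_bw(dz, st$a$nrm, p[[sprintf("%s%d_a_g", prefix, i)]],
                      h * w, B)
    g[[sprintf("%s%d_a_g", prefix, i)]] <- na$dg
    g[[sprintf("%s%d_a_be", prefix, i)]] <- na$db
    bwa <- conv3_bw(na$dx, st$a, p[[sprintf("%s%d_a_W", prefix, i)]], h, w, B)
    g[[sprintf("%s%d_a_W", prefix, i)]] <- bwa$dW
    g[[sprintf("%s%d_a_b", prefix, i)]] <- bwa$db
    dx <- cpp_bilinear_bw(bwa$dx, as.integer(st$h_in), as.integer(st$w_in),
                          as.integer(B), as.integer(h), as.integer(w))
    h <- st$h_in; w <- st$w_in
  }
  list(grads = g, dx = dx)
}
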