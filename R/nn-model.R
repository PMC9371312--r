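# Full-network forward and backward passes. The wiring follows the
# cross-task design: shared encoder+ASPP features feed (i) the coarse
# three-tissue decoder, whose soft masks gate the classification features
# (lesion attention), (ii) the classifier, whose per-class features and
# scores drive the category-selection features, and (iii) the fine lesion
# decoder fusing category-selection and gland-masked self-attention
# features. Gradients flow through the soft masks (they are never
# detached): the cross-task coupling is the point of the method.

lam_fw <- function(fprime, ml, mm, use_masks) {
  D <- nrow(fprime)
  if (use_masks) {
    s <- 1 + mm + ml
    flam <- fprime * rep(s, each = D)
  } else {
    s <- rep(1, ncol(fprime))
    flam <- fprime
  }
  list(flam = flam, s = s)
}

lam_bw <- function(dflam, fprime, cache, use_masks) {
  D <- nrow(fprime)
  dfp <- dflam * rep(cache$s, each = D)
  if (use_masks) {
    dm <- colSums(dflam * fprime)  # identical for gland and lesion masks
    list(dfp = dfp, dml = dm, dmm = dm)
  } else {
    z <- numeric(ncol(fprime))
    list(dfp = dflam, dml = z, dmm = z)
  }
}

cls_fw <- function(p, cfg, flam, Nf, B) {
  D1 <- as.integer(cfg$cls$d1)
  C <- as.integer(cfg$num_classes)
  pooled <- vapply(seq_len(B), function(b)
    rowMeans(flam[, (b - 1L) * Nf + seq_len(Nf), drop = FALSE]),
    numeric(nrow(flam)))
  pooled <- matrix(pooled, nrow(flam), B)
  Z <- p$cls_W1 %*% pooled + p$cls_b1
  logits <- matrix(0, C, B)
  for (cc in seq_len(C)) {
    rows <- (cc - 1L) * D1 + seq_len(D1)
    logits[cc, ] <- colSums(Z[rows, , drop = FALSE] * p$cls_u) + p$cls_b[cc]
  }
  h <- softmax_cols(logits)
  list(pooled = pooled, Z = Z, logits = logits, h = h)
}

cls_bw <- function(p, cfg, dlogits, dZ_extra, cache, Nf, B) {
  D1 <- as.integer(cfg$cls$d1)
  C <- as.integer(cfg$num_classes)
  dZ <- if (is.null(dZ_extra)) matrix(0, nrow(cache$Z), B) else dZ_extra
  du <- numeric(D1)
  db <- numeric(C)
  for (cc in seq_len(C)) {
    rows <- (cc - 1L) * D1 + seq_len(D1)
    dZ[rows, ] <- dZ[rows, , drop = FALSE] + outer(p$cls_u, dlogits[cc, ])
    du <- du + as.vector(cache$Z[rows, , drop = FALSE] %*% dlogits[cc, ])
    db[cc] <- sum(dlogits[cc, ])
  }
  g <- list(cls_W1 = dZ %*% t(cache$pooled),
            cls_b1 = rowSums(dZ),
            cls_u = du, cls_b = db)
  dpooled <- t(p$cls_W1) %*% dZ
  dflam <- dpooled[, rep(seq_len(B), each = Nf), drop = FALSE] / Nf
  list(grads = g, dflam = dflam)
}

csm_fw <- function(p, cfg, fprime, Z, h, Nf, B) {
  D1 <- as.integer(cfg$cls$d1)
  C <- as.integer(cfg$num_classes)
  P <- p$csm_P_W %*% fprime + p$csm_P_b
  out <- matrix(0, D1, Nf * B)
  Wg <- vector("list", B)
  for (b in seq_len(B)) {
    cols <- (b - 1L) * Nf + seq_len(Nf)
    Gb <- matrix(Z[, b], D1, C)
    Wgb <- p$csm_A %*% Gb + p$csm_a
    Whb <- Wgb * rep(h[, b], each = D1)
    out[, cols] <- Whb %*% P[, cols, drop = FALSE]
    Wg[[b]] <- Wgb
  }
  list(out = out, P = P, Wg = Wg)
}

csm_bw <- function(p, cfg, dcsm, cache, fprime, Z, h, Nf, B) {
  D1 <- as.integer(cfg$cls$d1)
  C <- as.integer(cfg$num_classes)
  dP <- matrix(0, C, Nf * B)
  dZ <- matrix(0, nrow(Z), B)
  dh <- matrix(0, C, B)
  dA <- matrix(0, D1, D1)
  da <- numeric(D1)
  for (b in seq_len(B)) {
    cols <- (b - 1L) * Nf + seq_len(Nf)
    Gb <- matrix(Z[, b], D1, C)
    Wgb <- cache$Wg[[b]]
    Whb <- Wgb * rep(h[, b], each = D1)
    dF <- dcsm[, cols, drop = FALSE]
    Pb <- cache$P[, cols, drop = FALSE]
    dWh <- dF %*% t(Pb)
    dP[, cols] <- t(Whb) %*% dF
    dWg <- dWh * rep(h[, b], each = D1)
    dh[, b] <- colSums(dWh * Wgb)
    dA <- dA + dWg %*% t(Gb)
    da <- da + rowSums(dWg)
    dZ[, b] <- as.vector(t(p$csm_A) %*% dWg)
  }
  g <- list(csm_A = dA, csm_a = da,
            csm_P_W = dP %*% t(fprime), csm_P_b = rowSums(dP))
  list(grads = g, dfp = t(p$csm_P_W) %*% dP, dZ = dZ, dh = dh)
}

akgm_fw <- function(p, fprime, mm, Nf, B) {
  Dp <- nrow(p$akgm_Wq)
  D <- nrow(fprime)
  out <- matrix(0, D, Nf * B)
  cache <- vector("list", B)
  for (b in seq_len(B)) {
    cols <- (b - 1L) * Nf + seq_len(Nf)
    fb <- fprime[, cols, drop = FALSE]
    m <- mm[cols]
    Q <- p$akgm_Wq %*% fb
    K <- p$akgm_Wk %*% fb
    V <- p$akgm_Wv %*% fb
    Qp <- Q * rep(m, each = Dp)
    Kp <- K * rep(m, each = Dp)
    S <- softmax_rows(crossprod(Qp, Kp))
    AV <- V %*% t(S)
    out[, cols] <- p$akgm_alpha * AV + fb
    cache[[b]] <- list(Q = Q, K = K, V = V, Qp = Qp, Kp = Kp, S = S,
                       AV = AV, m = m)
  }
  list(out = out, cache = cache)
}

akgm_bw <- function(p, dout, cache, fprime, Nf, B) {
  Dp <- nrow(p$akgm_Wq)
  dWq <- matrix(0, nrow(p$akgm_Wq), ncol(p$akgm_Wq))
  dWk <- matrix(0, nrow(p$akgm_Wk), ncol(p$akgm_Wk))
  dWv <- matrix(0, nrow(p$akgm_Wv), ncol(p$akgm_Wv))
  dalpha <- 0
  dfp <- matrix(0, nrow(fprime), ncol(fprime))
  dmm <- numeric(ncol(fprime))
  for (b in seq_len(B)) {
    cols <- (b - 1L) * Nf + seq_len(Nf)
    cb <- cache[[b]]
    fb <- fprime[, cols, drop = FALSE]
    dob <- dout[, cols, drop = FALSE]
    dalpha <- dalpha + sum(dob * cb$AV)
    dV <- p$akgm_alpha * dob %*% cb$S
    dS <- p$akgm_alpha * t(dob) %*% cb$V
    dE <- softmax_rows_bw(dS, cb$S)
    dQp <- cb$Kp %*% t(dE)
    dKp <- cb$Qp %*% dE
    mrep <- rep(cb$m, each = Dp)
    dQ <- dQp * mrep
    dK <- dKp * mrep
    dmm[cols] <- colSums(dQp * cb$Q) + colSums(dKp * cb$K)
    dWq <- dWq + dQ %*% t(fb)
    dWk <- dWk + dK %*% t(fb)
    dWv <- dWv + dV %*% t(fb)
    dfp[, cols] <- t(p$akgm_Wq) %*% dQ + t(p$akgm_Wk) %*% dK +
      t(p$akgm_Wv) %*% dV + dob
  }
  list(grads = list(akgm_Wq = dWq, akgm_Wk = dWk, akgm_Wv = dWv,
                    akgm_alpha = dalpha),
       dfp = dfp, dmm = dmm)
}

ctg_forward <- function(p, cfg, X, Himg, Wimg, B) {
  ea <- enc_aspp_fw(p, cfg, X, Himg, Wimg, B)
  fp <- ea$fprime; Hf <- ea$Hf; Wf <- ea$Wf; Nf <- Hf * Wf
  co <- decoder_fw(p, "cdec", p$chead_W, p$chead_b, fp, Hf, Wf, B, Himg, Wimg)
  Mprobs <- softmax_cols(co$logits_img)
  Mfeat <- cpp_bilinear_fw(Mprobs, as.integer(Himg), as.integer(Wimg),
                           as.integer(B), as.integer(Hf), as.integer(Wf))
  ml <- Mfeat[1, ]; mm <- Mfeat[2, ]
  lm <- lam_fw(fp, ml, mm, cfg$lam$use_masks)
  cl <- cls_fw(p, cfg, lm$flam, Nf, B)
  parts <- list()
  cs <- NULL; ak <- NULL
  if (cfg$fine$use_csm) {
    cs <- csm_fw(p, cfg, fp, cl$Z, cl$h, Nf, B)
    parts$csm <- cs$out
  }
  if (cfg$fine$use_akgm) {
    ak <- akgm_fw(p, fp, mm, Nf, B)
    parts$akgm <- ak$out
  }
  ffine <- do.call(rbind, unname(parts))
  fi <- decoder_fw(p, "fdec", p$fhead_W, p$fhead_b, ffine, Hf, Wf, B,
                   Himg, Wimg)
  Fprobs <- softmax_cols(fi$logits_img)
  list(fprime = fp, Hf = Hf, Wf = Wf, Nf = Nf,
       ea_cache = ea$cache, co_cache = co$cache, fi_cache = fi$cache,
       Mprobs = Mprobs, Mfeat = Mfeat, ml = ml, mm = mm,
       lam = lm, cls = cl, csm = cs, akgm = ak, ffine = ffine,
       Fprobs = Fprobs, Himg = Himg, Wimg = Wimg, B = B)
}

ctg_backward <- function(p, cfg, fwd, dlogits_cls, dMprobs, dFprobs) {
  B <- fwd$B; Nf <- fwd$Nf
  Himg <- fwd$Himg; Wimg <- fwd$Wimg
  g <- list()
  # fine head
  dflog <- softmax_cols_bw(dFprobs, fwd$Fprobs)
  fb <- decoder_bw(p, "fdec", p$fhead_W, dflog, fwd$fi_cache, B, Himg, Wimg)
  g[names(fb$grads)] <- fb$grads
  g$fhead_W <- fb$grads$head_W; g$fhead_b <- fb$grads$head_b
  g$head_W <- NULL; g$head_b <- NULL
  dffine <- fb$dx
  dfp <- matrix(0, nrow(fwd$fprime), ncol(fwd$fprime))
  dmm_att <- numeric(ncol(fwd$fprime))
  dZ_csm <- NULL
  dh_csm <- matrix(0, nrow(fwd$cls$h), B)
  off <- 0L
  if (cfg$fine$use_csm) {
    D1 <- as.integer(cfg$cls$d1)
    dcsm <- dffine[off + seq_len(D1), , drop = FALSE]
    off <- off + D1
    cbk <- csm_bw(p, cfg, dcsm, fwd$csm, fwd$fprime, fwd$cls$Z, fwd$cls$h,
                  Nf, B)
    g[names(cbk$grads)] <- cbk$grads
    dfp <- dfp + cbk$dfp
    dZ_csm <- cbk$dZ
    dh_csm <- dh_csm + cbk$dh
  }
  if (cfg$fine$use_akgm) {
    D <- as.integer(cfg$backbone$channels)
    dak <- dffine[off + seq_len(D), , drop = FALSE]
    abk <- akgm_bw(p, dak, fwd$akgm$cache, fwd$fprime, Nf, B)
    g[names(abk$grads)] <- abk$grads
    dfp <- dfp + abk$dfp
    dmm_att <- dmm_att + abk$dmm
  } else {
    g$akgm_Wq <- 0 * p$akgm_Wq; g$akgm_Wk <- 0 * p$akgm_Wk
    g$akgm_Wv <- 0 * p$akgm_Wv; g$akgm_alpha <- 0
  }
  # classification head: CE gradient plus the CSM path through the scores
  dlog_total <- dlogits_cls + softmax_cols_bw(dh_csm, fwd$cls$h)
  clb <- cls_bw(p, cfg, dlog_total, dZ_csm, fwd$cls, Nf, B)
  g[names(clb$grads)] <- clb$grads
  lmb <- lam_bw(clb$dflam, fwd$fprime, fwd$lam, cfg$lam$use_masks)
  dfp <- dfp + lmb$dfp
  # soft-mask gradients (attention paths) back to image-resolution probs
  dMfeat <- matrix(0, 3L, ncol(fwd$fprime))
  dMfeat[1, ] <- lmb$dml
  dMfeat[2, ] <- lmb$dmm + dmm_att
  dM_att <- cpp_bilinear_bw(dMfeat, as.integer(Himg), as.integer(Wimg),
                            as.integer(B), as.integer(fwd$Hf),
                            as.integer(fwd$Wf))
  dM_total <- dMprobs + dM_att
  dclog <- softmax_cols_bw(dM_total, fwd$Mprobs)
  cb <- decoder_bw(p, "cdec", p$chead_W, dclog, fwd$co_cache, B, Himg, Wimg)
  g[names(cb$grads)] <- cb$grads
  g$chead_W <- cb$grads$head_W; g$chead_b <- cb$grads$head_b
  g$head_W <- NULL; g$head_b <- NULL
  dfp <- dfp + cb$dx
  eb <- enc_aspp_bw(p, cfg, fwd$ea_cache, dfp, B)
  g[names(eb$grads)] <- eb$grads
  g
}

# ---- losses with gradients --------------------------------------------------

dice_loss_grad <- function(probs, target, B, eps = 1) {
  C <- nrow(probs)
  N <- ncol(probs) %/% B
  loss <- 0
  grad <- matrix(0, C, ncol(probs))
  for (b in seq_len(B)) {
    cols <- (b - 1L) * N + seq_len(N)
    pb <- probs[, cols, drop = FALSE]
    tb <- target[, cols, drop = FALSE]
    sp <- rowSums(pb); st <- rowSums(tb); spt <- rowSums(pb * tb)
    den <- sp + st + eps
    dice <- (2 * spt + eps) / den
    loss <- loss + (1 - mean(dice))
    # length-C vectors recycle down the channel dimension (column-major)
    grad[, cols] <- -(2 * tb * den - (2 * spt + eps)) / den^2 / (C * B)
  }
  list(loss = loss / B, grad = grad)
}

ce_loss_grad <- function(h, labels1, B) {
  idx <- cbind(labels1, seq_len(B))
  loss <- mean(-log(pmax(h[idx], 1e-12)))
  Y <- matrix(0, nrow(h), B)
  Y[idx] <- 1
  list(loss = loss, dlogits = (h - Y) / B)
}

# ---- Adam -------------------------------------------------------------------

adam_init <- function(params) {
  list(m = lapply(params, function(x) x * 0),
       v = lapply(params, function(x) x * 0),
       t = 0L)
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.99,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    gval <- grads[[nm]]
    if (is.null(gval)) next
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * gval
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * gval * gval
    mhat <- state$m[[nm]] / bc1
    vhat <- state$v[[nm]] / bc2
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}
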