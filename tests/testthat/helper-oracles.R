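# naive loop-based references for the two attention modules, written
# directly from their defining equations
csm_reference <- function(f, pred, params) {
  d <- dim(f$values)
  D1 <- nrow(params$csm_A); C <- length(pred$h_score)
  N <- d[2] * d[3]
  Wg <- matrix(0, D1, C)
  for (cc in seq_len(C))
    Wg[, cc] <- params$csm_A %*% pred$g_global[, cc] + params$csm_a
  P <- matrix(0, C, N)
  fp <- matrix(f$values, d[1], N)
  for (cc in seq_len(C))
    for (n in seq_len(N))
      P[cc, n] <- sum(params$csm_P_W[cc, ] * fp[, n]) + params$csm_P_b[cc]
  out <- matrix(0, D1, N)
  for (d1 in seq_len(D1))
    for (n in seq_len(N))
      out[d1, n] <- sum(Wg[d1, ] * pred$h_score * P[, n])
  array(out, c(D1, d[2], d[3]))
}

akgm_reference <- function(f, m, params, alpha = params$akgm_alpha) {
  d <- dim(f$values)
  N <- d[2] * d[3]
  fp <- matrix(f$values, d[1], N)
  mv <- as.numeric(m)
  Q <- params$akgm_Wq %*% fp
  K <- params$akgm_Wk %*% fp
  V <- params$akgm_Wv %*% fp
  Qp <- Q; Kp <- K
  for (n in seq_len(N)) { Qp[, n] <- Q[, n] * mv[n]; Kp[, n] <- K[, n] * mv[n] }
  E <- matrix(0, N, N)
  for (j in seq_len(N)) for (i in seq_len(N)) E[j, i] <- sum(Qp[, j] * Kp[, i])
  S <- matrix(0, N, N)
  for (j in seq_len(N)) S[j, ] <- exp(E[j, ] - max(E[j, ])) /
    sum(exp(E[j, ] - max(E[j, ])))
  out <- fp
  for (j in seq_len(N)) {
    acc <- numeric(d[1])
    for (i in seq_len(N)) acc <- acc + S[j, i] * V[, i]
    out[, j] <- alpha * acc + fp[, j]
  }
  list(out = array(out, d), S = S)
}


# independent set-arithmetic reference: masks as explicit coordinate sets
seg_reference <- function(pred, truth) {
  Ap <- which(pred != 0)
  Ag <- which(truth != 0)
  inter <- length(intersect(Ag, Ap))
  uni <- length(union(Ag, Ap))
  fp <- length(setdiff(union(Ag, Ap), Ag))
  list(dsc = 2 * inter / (length(Ag) + length(Ap)),
       ji = inter / uni, tpr = inter / length(Ag),
       fpr = fp / uni, tfpr = fp / length(Ag))
}

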