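test_that("CSM matches its loop-based reference on random inputs", {
  cfg <- tiny_cfg()
  set.seed(40)
  for (sp in c(2L, 4L)) {
    for (trial in 1:5) {
      p <- ctg_init(cfg, seed = trial)
      f <- as_shared_features(array(rnorm(8 * sp * sp), c(8, sp, sp)),
                              c(32, 32))
      h <- runif(2); h <- h / sum(h)
      pred <- as_class_prediction(matrix(rnorm(8), 4, 2), h)
      expect_equal(csm(f, pred, p), csm_reference(f, pred, p),
                   tolerance = 1e-6)
    }
  }
})

test_that("CSM degenerate score vectors behave per the equation", {
  cfg <- tiny_cfg()
  p <- ctg_init(cfg, seed = 8)
  f <- as_shared_features(array(rnorm(8 * 4), c(8, 2, 2)), c(32, 32))
  G <- matrix(rnorm(8), 4, 2)

  # all-zero scores (synthetic, unreachable from a softmax) zero the output
  z <- csm(f, as_class_prediction(G, c(0, 0)), p)
  expect_true(all(z == 0))

  # one-hot scores leave a single outer product u (x) p1
  oh <- csm(f, as_class_prediction(G, c(1, 0)), p)
  u <- as.vector(p$csm_A %*% G[, 1] + p$csm_a)
  P1 <- as.vector(p$csm_P_W[1, ] %*% matrix(f$values, 8, 4)) + p$csm_P_b[1]
  expect_equal(matrix(oh, 4, 4), outer(u, P1), tolerance = 1e-9)

  # duplicate classes at (0.5, 0.5) equal the single-class result
  Gd <- cbind(G[, 1], G[, 1])
  pd <- p
  pd$csm_P_W[2, ] <- pd$csm_P_W[1, ]
  pd$csm_P_b[2] <- pd$csm_P_b[1]
  dup <- csm(f, as_class_prediction(Gd, c(0.5, 0.5)), pd)
  single <- csm(f, as_class_prediction(Gd, c(1, 0)), pd)
  expect_equal(dup, single, tolerance = 1e-9)

  expect_error(csm(f, as_class_prediction(matrix(rnorm(12), 4, 3),
                                          c(0.3, 0.3, 0.4)), p),
               "class count mismatch")
})

test_that("AKGM matches its loop-based reference and normalises rows", {
  cfg <- tiny_cfg()
  set.seed(41)
  for (sp in c(2L, 4L)) {
    for (trial in 1:5) {
      p <- ctg_init(cfg, seed = trial + 50)
      p$akgm_alpha <- 0.7
      f <- as_shared_features(array(rnorm(8 * sp * sp), c(8, sp, sp)),
                              c(32, 32))
      m <- matrix(runif(sp * sp), sp, sp)
      ref <- akgm_reference(f, m, p)
      expect_equal(akgm(f, m, p), ref$out, tolerance = 1e-6)
      expect_equal(rowSums(ref$S), rep(1, sp * sp), tolerance = 1e-5)
      # the implementation's attention rows are stochastic too
      st <- ctgnet:::akgm_fw(p, matrix(f$values, 8, sp * sp),
                             as.numeric(m), sp * sp, 1L)
      expect_equal(rowSums(st$cache[[1]]$S), rep(1, sp * sp),
                   tolerance = 1e-5)
    }
  }
})

test_that("AKGM is exactly the identity at its initial alpha", {
  cfg <- tiny_cfg()
  p <- ctg_init(cfg, seed = 9)
  expect_identical(p$akgm_alpha, 0)
  f <- as_shared_features(array(rnorm(8 * 16), c(8, 4, 4)), c(32, 32))
  m <- matrix(runif(16), 4, 4)
  expect_identical(akgm(f, m, p), f$values)
})

test_that("an all-zero gland mask yields uniform attention", {
  cfg <- tiny_cfg()
  p <- ctg_init(cfg, seed = 10)
  p$akgm_alpha <- 1.3
  f <- as_shared_features(array(rnorm(8 * 4), c(8, 2, 2)), c(32, 32))
  m <- matrix(0, 2, 2)
  out <- akgm(f, m, p)
  fp <- matrix(f$values, 8, 4)
  vbar <- rowMeans(p$akgm_Wv %*% fp)
  expect_equal(matrix(out, 8, 4), fp + 1.3 * vbar, tolerance = 1e-9)
})

test_that("fine segmentation outputs normalised full-resolution maps", {
  cfg <- tiny_cfg()
  p <- ctg_init(cfg, seed = 11)
  f_csm <- array(rnorm(4 * 16), c(4, 4, 4))
  f_akgm <- array(rnorm(8 * 16), c(8, 4, 4))
  ff <- fine_features(f_csm, f_akgm, c(32, 32))
  expect_identical(dim(ff$f_fine), c(12L, 4L, 4L))
  out <- fine_segment(ff, p)
  expect_identical(dim(out), c(2L, 32L, 32L))
  sums <- apply(out, 2:3, sum)
  expect_true(max(abs(sums - 1)) < 1e-10)

  # zero head parameters give 0.5 everywhere
  p0 <- p
  p0$fhead_W[] <- 0; p0$fhead_b[] <- 0
  expect_equal(max(abs(fine_segment(ff, p0) - 0.5)), 0, tolerance = 1e-12)
  expect_error(fine_features(NULL, NULL, c(32, 32)), "at least one")
})

test_that("all three fine-feature wirings build and train one step", {
  train <- tiny_phantoms(4, seed = 21)
  variants <- list(c(TRUE, FALSE), c(FALSE, TRUE), c(TRUE, TRUE))
  for (v in variants) {
    cfg <- tiny_cfg(fine = list(use_csm = v[1], use_akgm = v[2]),
                    train = list(max_epochs = 1L, batch_size = 4L))
    fit <- ctgnet_fit(train, config = cfg, seed = 1)
    expect_s3_class(fit, "ctgnet")
    expect_identical(nrow(fit$log), 1L)
    expect_true(is.finite(fit$log$l_total))
  }
})
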