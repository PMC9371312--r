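test_that("segmentation metrics match the printed formulas exactly", {
  g <- matrix(0L, 20, 20); g[1:10, 1:10] <- 1L   # |Ag| = 100
  p <- matrix(0L, 20, 20); p[1:10, 5:10] <- 1L   # 60 px overlapping truth
  p[11:20, 1:2] <- 1L                            # plus 20 false positives
  m <- seg_metrics(p, g)
  expect_equal(m$dsc, 120 / 180)
  expect_equal(m$ji, 60 / 120)
  expect_equal(m$tpr, 0.6)
  expect_equal(m$fpr, 20 / 120)
  expect_equal(m$tfpr, 20 / 100)

  perfect <- seg_metrics(g, g)
  expect_equal(unlist(perfect[c("dsc", "ji", "tpr")]),
               c(dsc = 1, ji = 1, tpr = 1))
  expect_equal(unlist(perfect[c("fpr", "tfpr")]), c(fpr = 0, tfpr = 0))
})

test_that("tumour-normalised FPR can exceed one", {
  g <- matrix(0L, 12, 12); g[1:4, 1:3] <- 1L           # 12 px
  p <- matrix(0L, 12, 12); p[1:12, 1:3] <- 1L          # 36 px, superset
  m <- seg_metrics(p, g)
  expect_equal(m$tfpr, 2)
  expect_gt(m$tfpr, 1)
})

test_that("metrics agree with a coordinate-set reference on random masks", {
  set.seed(101)
  for (i in 1:200) {
    p <- matrix(rbinom(256, 1, runif(1, 0.1, 0.6)), 16, 16)
    g <- matrix(rbinom(256, 1, runif(1, 0.1, 0.6)), 16, 16)
    if (sum(g) == 0) g[1, 1] <- 1L
    m <- seg_metrics(p, g)
    r <- seg_reference(p, g)
    expect_identical(unlist(m[names(r)]), unlist(r))
    # DSC/JI algebraic identity
    expect_equal(m$dsc, 2 * m$ji / (1 + m$ji), tolerance = 1e-9)
  }
})

test_that("empty-mask conventions are as documented", {
  z <- matrix(0L, 8, 8)
  nz <- z; nz[1:2, 1:2] <- 1L
  both <- seg_metrics(z, z)
  expect_equal(unlist(both),
               c(dsc = 1, ji = 1, tpr = 1, fpr = 0, tfpr = 0))
  fponly <- seg_metrics(nz, z)
  expect_equal(unlist(fponly[c("dsc", "ji", "tpr", "fpr")]),
               c(dsc = 0, ji = 0, tpr = 0, fpr = 1))
  expect_true(is.na(fponly$tfpr))
  miss <- seg_metrics(z, nz)
  expect_equal(unlist(miss),
               c(dsc = 0, ji = 0, tpr = 0, fpr = 0, tfpr = 0))
})

test_that("classification metrics reproduce the confusion-count formulas", {
  # TP=8, FN=2, TN=9, FP=1
  labels <- c(rep(1, 10), rep(0, 10))
  scores <- c(rep(0.9, 8), rep(0.1, 2), rep(0.2, 9), 0.8)
  m <- cls_metrics(scores, labels)
  expect_equal(m$sen, 0.8)
  expect_equal(m$spc, 0.9)
  expect_equal(m$acc, 0.85)
  expect_equal(m$pre, 8 / 9)
  expect_equal(m$f1, 2 * (8 / 9) * 0.8 / (8 / 9 + 0.8), tolerance = 1e-9)
  expect_equal(m$f1, 0.8421, tolerance = 1e-4)
})

test_that("AUC behaves like the Mann-Whitney statistic", {
  sep <- cls_metrics(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0))
  expect_equal(sep$auc, 1)
  expect_equal(sep$acc, 1)

  set.seed(7)
  n <- 2000
  scores <- runif(n)
  labels <- rbinom(n, 1, 0.5)
  m <- cls_metrics(scores, labels)
  expect_lt(abs(m$auc - 0.5), 3 / sqrt(n))

  # invariant under strictly monotone transformation
  m2 <- cls_metrics(qlogis(scores * 0.98 + 0.01), labels, threshold = 0)
  expect_equal(m2$auc, m$auc)

  # midrank tie handling agrees with an established implementation
  skip_if_not_installed("pROC")
  set.seed(8)
  s <- sample(seq(0, 1, by = 0.1), 60, replace = TRUE)
  l <- rbinom(60, 1, 0.5)
  expect_equal(cls_metrics(s, l)$auc,
               as.numeric(pROC::auc(pROC::roc(l, s, quiet = TRUE,
                                              levels = c(0, 1),
                                              direction = "<"))),
               tolerance = 1e-12)
})

test_that("degenerate label sets leave AUC undefined but keep the rest", {
  expect_warning(m <- cls_metrics(c(0.9, 0.8), c(1, 1)), "AUC undefined")
  expect_true(is.na(m$auc))
  expect_equal(m$acc, 1)
})

test_that("aggregation averages segmentation per image, pools classification", {
  g1 <- matrix(0L, 8, 8); g1[1:4, 1:4] <- 1L
  p1 <- g1
  g2 <- matrix(0L, 8, 8); g2[1:4, 1:4] <- 1L
  p2 <- matrix(0L, 8, 8); p2[1:4, 3:4] <- 1L  # dsc = 16/24
  s1 <- seg_metrics(p1, g1); s2 <- seg_metrics(p2, g2)
  one <- aggregate_metrics(list(s1))
  expect_equal(one$dsc, s1$dsc)
  two <- aggregate_metrics(list(s1, s2))
  expect_equal(two$dsc, mean(c(s1$dsc, s2$dsc)))

  scores <- c(0.9, 0.2, 0.7, 0.4)
  labels <- c(1, 0, 0, 1)
  agg <- aggregate_metrics(list(s1, s2), scores, labels)
  pooled <- cls_metrics(scores, labels)
  expect_equal(agg$auc, pooled$auc)
  expect_error(aggregate_metrics(list()), "empty")
})
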