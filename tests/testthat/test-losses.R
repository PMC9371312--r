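test_that("Dice loss limits match closed-form arithmetic", {
  # perfect overlap on masks of >= 1000 px per class
  t <- array(0, c(2, 40, 40))
  t[1, 1:20, ] <- 1; t[2, , ] <- 1 - t[1, , ]
  expect_lt(dice_loss(t, t), 1e-3)

  # disjoint hard masks on a 4x4 grid, single class channel pair:
  # class 1: pred 8 px vs target 8 px disjoint -> (0+1)/(8+8+1) = 1/17;
  # class 2 is its complement with the same counts
  p <- array(0, c(2, 4, 4)); tt <- array(0, c(2, 4, 4))
  p[1, 1:2, ] <- 1; p[2, , ] <- 1 - p[1, , ]
  tt[1, 3:4, ] <- 1; tt[2, , ] <- 1 - tt[1, , ]
  # per-class dice: class1 = 1/17; class2 overlap 0 -> also 1/17
  expect_equal(dice_loss(p, tt), 1 - 1 / 17, tolerance = 1e-12)

  # uniform 0.5 prediction, target covering half of n = 10000 pixels
  n <- 10000
  pu <- array(0.5, c(2, 100, 100))
  tu <- array(0, c(2, 100, 100))
  tu[1, 1:50, ] <- 1; tu[2, , ] <- 1 - tu[1, , ]
  # per-class dice = (2*0.5*n/2 + 1)/(0.5n + n/2 + 1) ~ 0.5
  expect_equal(dice_loss(pu, tu), 0.5, tolerance = 1e-3)
})

test_that("Dice loss is invariant to class relabelling", {
  set.seed(3)
  p <- array(runif(3 * 64), c(3, 8, 8))
  p <- sweep(p, 2:3, apply(p, 2:3, sum), "/")
  lab <- sample(0:2, 64, replace = TRUE)
  t <- array(0, c(3, 8, 8))
  for (k in 0:2) t[k + 1, , ][matrix(lab == k, 8, 8)] <- 1
  perm <- c(3, 1, 2)
  expect_equal(dice_loss(p, t), dice_loss(p[perm, , ], t[perm, , ]),
               tolerance = 1e-12)
  expect_error(dice_loss(p, t[1:2, , ]), "mismatch")
})

test_that("cross-entropy matches closed forms", {
  expect_equal(cls_loss(c(1, 0), 0), 0)
  expect_equal(cls_loss(c(0.5, 0.5), 1), log(2))
  expect_equal(cls_loss(c(0.75, 0.25), 1), -log(0.25))
  expect_equal(cls_loss(c(0.75, 0.25), 1), 1.3863, tolerance = 1e-4)
  expect_error(cls_loss(c(0.5, 0.5), 2), "out of range")
})

test_that("DWA weights follow the loss-descent-ratio softmax", {
  st <- task_weight_state()
  expect_equal(dwa_update(st, 1)$weights, c(1, 1))
  expect_equal(dwa_update(st, 2)$weights, c(1, 1))

  # equal loss ratios for both tasks -> unit weights
  st$loss_history <- list(c(1.0, 0.5), c(0.8, 0.4))
  expect_equal(dwa_update(st, 3)$weights, c(1, 1))

  # w = (0.8, 0.9), T = 2
  st$loss_history <- list(c(1.0, 0.8), c(1.0, 0.9))
  lam <- dwa_update(st, 3)$weights
  expect_equal(lam[1], 2 * exp(0.4) / (exp(0.4) + exp(0.45)),
               tolerance = 1e-12)
  expect_equal(lam, c(0.9750, 1.0250), tolerance = 1e-4)

  # T -> infinity limit
  st$temperature <- 1e9
  expect_equal(dwa_update(st, 3)$weights, c(1, 1), tolerance = 1e-9)

  st2 <- task_weight_state()
  st2$loss_history <- list(c(1, 0), c(1, 1))
  expect_error(dwa_update(st2, 3), "nonpositive|non-finite")
})

test_that("DWA matches brute-force re-evaluation on random histories", {
  set.seed(11)
  for (i in 1:50) {
    nt <- 2L
    len <- sample(3:8, 1)
    hist <- replicate(nt, runif(len, 0.05, 2), simplify = FALSE)
    st <- task_weight_state()
    st$loss_history <- hist
    t <- len + 1L
    lam <- dwa_update(st, t)$weights
    w <- vapply(hist, function(h) h[t - 1] / h[t - 2], numeric(1))
    ref <- nt * exp(w / 2) / sum(exp(w / 2))
    expect_equal(lam, ref, tolerance = 1e-10)
    expect_equal(sum(lam), 2, tolerance = 1e-10)
    expect_true(all(lam > 0))
  }
})

test_that("the joint loss combines components per the task weighting", {
  lb <- total_loss(0.2, 0.3, 0.1, c(1, 1))
  expect_equal(lb$l_total, 0.6)
  expect_equal(total_loss(0, 0, 0, c(1, 1))$l_total, 0)
  expect_equal(total_loss(0.7, 0.3, 0.2, c(1.5, 0))$l_total, 1.5 * 0.7)
  st <- task_weight_state()
  st$weights <- c(0.9, 1.1)
  expect_equal(total_loss(1, 1, 1, st)$l_total, 0.9 + 1.1 * 2)
})
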