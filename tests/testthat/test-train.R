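test_that("training runs the schedule and logs balanced task weights", {
  train <- tiny_phantoms(12, seed = 14)
  val <- tiny_phantoms(6, seed = 15)
  cfg <- tiny_cfg(train = list(max_epochs = 3L, batch_size = 4L))
  fit <- ctgnet_fit(train, val, config = cfg, seed = 2)
  expect_identical(nrow(fit$log), 3L)
  expect_equal(fit$log$lambda1 + fit$log$lambda2, rep(2, 3),
               tolerance = 1e-6)
  expect_true(all(is.finite(fit$log$val_l_total)))
  expect_true(all(c("l_cls", "l_cseg", "l_fseg") %in% names(fit$log)))
})

test_that("fits are reproducible for identical config and seed", {
  train <- tiny_phantoms(8, seed = 16)
  val <- tiny_phantoms(4, seed = 17)
  cfg <- tiny_cfg(train = list(max_epochs = 2L, batch_size = 4L))
  f1 <- ctgnet_fit(train, val, config = cfg, seed = 5)
  f2 <- ctgnet_fit(train, val, config = cfg, seed = 5)
  expect_equal(tail(f1$log$val_l_total, 1), tail(f2$log$val_l_total, 1),
               tolerance = 1e-6)
  expect_identical(f1$params$enc_s1_c1_W, f2$params$enc_s1_c1_W)
})

test_that("early stopping cannot trigger before patience+1 epochs", {
  train <- tiny_phantoms(8, seed = 18)
  val <- tiny_phantoms(4, seed = 19)
  cfg <- tiny_cfg(train = list(max_epochs = 6L, batch_size = 4L,
                               patience = 2L))
  fit <- ctgnet_fit(train, val, config = cfg, seed = 3)
  if (fit$epochs_run < 6L) expect_gte(fit$epochs_run, 3L)
  expect_gte(fit$best_epoch, 1L)
})

test_that("prediction is deterministic and respects the output contract", {
  train <- tiny_phantoms(6, seed = 20)
  cfg <- tiny_cfg(train = list(max_epochs = 1L, batch_size = 6L))
  fit <- ctgnet_fit(train, config = cfg, seed = 4)
  newdata <- tiny_phantoms(5, seed = 22)
  p1 <- predict(fit, newdata)
  p2 <- predict(fit, newdata)
  expect_identical(p1$scores, p2$scores)
  expect_identical(p1$fine_prob, p2$fine_prob)
  expect_identical(dim(p1$scores), c(5L, 2L))
  expect_length(p1$fine_mask, 5L)
  expect_length(p1$coarse_label, 5L)
  expect_equal(rowSums(p1$scores), rep(1, 5), tolerance = 1e-6)

  # zeroed fine head: every pixel at probability exactly 0.5
  fit0 <- fit
  fit0$params$fhead_W[] <- 0
  fit0$params$fhead_b[] <- 0
  pr0 <- predict(fit0, tiny_phantoms(1, seed = 23, lesion_probability = 0))
  expect_equal(max(abs(pr0$fine_prob[[1]] - 0.5)), 0, tolerance = 1e-12)
})

test_that("residuals, simulate and accessor methods behave", {
  train <- tiny_phantoms(4, seed = 24)
  attr(train, "phantom_config") <- tiny_phantom_cfg(seed = 24)
  cfg <- tiny_cfg(train = list(max_epochs = 1L, batch_size = 4L))
  fit <- ctgnet_fit(train, config = cfg, seed = 6)
  r <- residuals(fit, train)
  expect_length(r, 4L)
  expect_true(all(abs(r[[1]]) <= 1))
  sims <- simulate(fit, nsim = 2, seed = 9)
  expect_length(sims, 2L)
  expect_s3_class(sims[[1]], "phantom_sample")
  expect_named(coef(fit), names(fit$params))
  expect_output(print(fit), "Cross-task guided network")
  expect_output(print(summary(fit)), "parameters")
})

test_that("run_experiment produces the full metrics schema reproducibly", {
  cf <- list(
    phantom = list(image_height = 32, image_width = 32,
                   lesion_radius_range = c(3, 5)),
    model = list(desk_profile = TRUE, image_size = 32L,
                 backbone = list(base = 2L, channels = 8L),
                 cls = list(d1 = 4L)),
    train = list(max_epochs = 2L, batch_size = 4L),
    experiment = list(n_train = 8L, n_val = 4L, n_test = 4L, seed = 3L))
  d1 <- withr::local_tempdir()
  res <- run_experiment(cf, out_dir = d1)
  expect_true(file.exists(res$paths$metrics))
  m <- utils::read.csv(res$paths$metrics)
  expect_identical(names(m), c("dsc", "ji", "tpr", "fpr", "tfpr", "auc",
                               "acc", "sen", "spc", "pre", "f1"))
  expect_true(file.exists(res$paths$log))
  expect_true(file.exists(res$paths$config))

  d2 <- withr::local_tempdir()
  res2 <- run_experiment(cf, out_dir = d2)
  expect_equal(res$metrics, res2$metrics, tolerance = 1e-6)
})

test_that("checkpoints embed and enforce their configuration", {
  train <- tiny_phantoms(4, seed = 26)
  cfg <- tiny_cfg(train = list(max_epochs = 1L, batch_size = 4L))
  fit <- ctgnet_fit(train, config = cfg, seed = 7)
  path <- withr::local_tempfile(fileext = ".rds")
  save_ctgnet(fit, path)
  back <- load_ctgnet(path)
  expect_identical(back$params, fit$params)
  expect_silent(load_ctgnet(path, config = cfg))
  other <- tiny_cfg(num_classes = 3L)
  expect_error(load_ctgnet(path, config = other), "mismatch")
})

test_that("training rejects inconsistent inputs", {
  cfg <- tiny_cfg()
  expect_error(ctgnet_fit(list(), config = cfg), "empty")
  bad <- tiny_phantoms(2, seed = 27, classes = "threeclass",
                       lesion_probability = 1, malignant_fraction = 1)
  expect_error(ctgnet_fit(bad, config = tiny_cfg(num_classes = 2L)),
               "class labels")
  wrong_size <- generate_dataset(phantom_config(seed = 1), 2)
  expect_error(ctgnet_fit(wrong_size, config = cfg), "image_size")
})
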