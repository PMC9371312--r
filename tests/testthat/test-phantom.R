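test_that("generation is deterministic in (config, index)", {
  cfg <- phantom_config(seed = 7)
  a <- generate_phantom(cfg, 3)
  b <- generate_phantom(cfg, 3)
  expect_identical(a$image, b$image)
  expect_identical(a$coarse_mask, b$coarse_mask)
  expect_identical(a$lesion_mask, b$lesion_mask)
  expect_identical(a$class_label, b$class_label)
  d <- generate_phantom(cfg, 4)
  expect_false(identical(a$image, d$image))
})

test_that("lesion_probability = 0 forces normal samples", {
  cfg <- phantom_config(lesion_probability = 0, seed = 2)
  for (i in 0:4) {
    s <- generate_phantom(cfg, i)
    expect_identical(s$class_label, 0L)
    expect_true(all(s$lesion_mask == 0L))
  }
})

test_that("mask invariants hold across generated samples", {
  cfg <- phantom_config(lesion_probability = 0.7, seed = 5)
  for (i in 0:19) {
    s <- generate_phantom(cfg, i)
    # lesion pixels are labelled lesion in the coarse mask
    expect_true(all(s$coarse_mask[s$lesion_mask == 1L] == 2L))
    # lesions only inside the gland band rows
    gr <- s$metadata$gland_rows
    lesion_rows <- which(rowSums(s$lesion_mask) > 0)
    if (length(lesion_rows))
      expect_true(min(lesion_rows) >= gr[1] && max(lesion_rows) <= gr[2])
    # label 0 iff the lesion mask is empty
    expect_identical(s$class_label == 0L, sum(s$lesion_mask) == 0L)
    expect_true(all(s$coarse_mask %in% 0:2))
    expect_true(all(s$lesion_mask %in% 0:1))
    expect_true(all(s$image >= 0 & s$image <= 1))
  }
})

test_that("benign lesion pixel count tracks the configured radius range", {
  cfg <- phantom_config(seed = 7, lesion_probability = 1,
                        malignant_fraction = 0)
  s <- generate_phantom(cfg, 0)
  n <- sum(s$lesion_mask)
  rr <- cfg$lesion_radius_range
  expect_gte(n, pi * rr[1]^2)
  expect_lte(n, pi * rr[2]^2 * 1.1)
})

test_that("empirical lesion frequency matches lesion_probability", {
  p <- 0.5
  n <- 200L
  cfg <- phantom_config(lesion_probability = p, seed = 31)
  labs <- vapply(generate_dataset(cfg, n),
                 function(s) s$class_label > 0L, logical(1))
  expect_lt(abs(mean(labs) - p), 4 * sqrt(p * (1 - p) / n))
})

test_that("lesions are hypoechoic relative to the surrounding gland", {
  cfg <- phantom_config(lesion_probability = 1, seed = 13)
  for (i in 0:9) {
    s <- generate_phantom(cfg, i)
    clean <- s$metadata$clean
    les <- s$lesion_mask == 1L
    gland <- s$coarse_mask == 1L
    expect_lt(mean(clean[les]), mean(clean[gland]))
    # after speckle, with tolerance (unit-mean noise preserves contrast)
    expect_lt(mean(s$image[les]), mean(s$image[gland]) + 0.05)
  }
})

test_that("invalid configurations are rejected", {
  expect_error(phantom_config(skin_band_fraction = 0.3), "skin_band")
  expect_error(phantom_config(gland_band_fraction = 0.1), "gland_band")
  expect_error(phantom_config(lesion_radius_range = c(5, 30)),
               "gland band height")
  expect_error(phantom_config(contrast_lesion = 0.1), "contrast_lesion")
  expect_error(phantom_config(speckle_strength = -1), "speckle")
})

test_that("datasets round-trip through disk losslessly", {
  dir <- withr::local_tempdir()
  samples <- tiny_phantoms(3, seed = 9, lesion_probability = 1)
  manifest <- write_dataset(samples, dir)
  back <- read_dataset(manifest)
  expect_length(back, 3L)
  for (i in 1:3) {
    expect_identical(back[[i]]$coarse_mask, samples[[i]]$coarse_mask)
    expect_identical(back[[i]]$lesion_mask, samples[[i]]$lesion_mask)
    expect_identical(back[[i]]$class_label, samples[[i]]$class_label)
    # image is 8-bit quantised
    expect_lt(max(abs(back[[i]]$image - samples[[i]]$image)), 1 / 255)
  }
})

test_that("writing is byte-identical across calls", {
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  samples <- tiny_phantoms(2, seed = 4)
  write_dataset(samples, d1)
  write_dataset(samples, d2)
  for (f in list.files(d1)) {
    expect_identical(readBin(file.path(d1, f), "raw", 1e6),
                     readBin(file.path(d2, f), "raw", 1e6))
  }
})

test_that("manifest edge cases and errors", {
  dir <- withr::local_tempdir()
  m0 <- write_dataset(list(), dir)
  expect_identical(nrow(utils::read.csv(m0)), 0L)

  dir2 <- withr::local_tempdir()
  samples <- generate_dataset(tiny_phantom_cfg(seed = 1,
                                               lesion_probability = 0.5), 10)
  m <- write_dataset(samples, dir2)
  expect_identical(nrow(utils::read.csv(m)), 10L)

  # a normal sample survives the round trip
  norm <- generate_dataset(tiny_phantom_cfg(seed = 2,
                                            lesion_probability = 0), 1)
  dir3 <- withr::local_tempdir()
  back <- read_dataset(write_dataset(norm, dir3))
  expect_identical(back[[1]]$class_label, 0L)
  expect_true(all(back[[1]]$lesion_mask == 0L))

  # missing file is reported by name
  bad <- file.path(dir3, "sample_00000.png")
  file.remove(bad)
  expect_error(read_dataset(file.path(dir3, "manifest.csv")),
               "sample_00000.png")
})
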