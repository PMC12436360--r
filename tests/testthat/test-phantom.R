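# Phantom generator: determinism, geometry invariants, dataset plumbing.

cfg64 <- phantomConfig(imageSize = 64L, seed = 3L)

test_that("rendering is a deterministic function of (seed, label, site, config)", {
  a <- renderPhantom(11L, 1L, "medial", cfg64)
  b <- renderPhantom(11L, 1L, "medial", cfg64)
  expect_identical(a@pixels, b@pixels)
  expect_false(identical(a@pixels, renderPhantom(12L, 1L, "medial", cfg64)@pixels))
})

test_that("sample invariants hold: roi in bounds, site iff label, intensities in [0,1]", {
  for (seed in 1:10) {
    lab <- seed %% 2L
    s <- renderPhantom(seed, lab, if (lab == 1L) "floor" else "none", cfg64)
    expect_true(validObject(s))
    expect_true(all(s@pixels >= 0 & s@pixels <= 1))
    expect_true(s@roi[1] >= 0 && s@roi[3] <= nrow(s@pixels))
  }
  expect_error(renderPhantom(1L, 1L, "none", cfg64), "site")
  expect_error(renderPhantom(1L, 0L, "floor", cfg64), "site")
})

test_that("normal phantoms have symmetric orbital rims relative to the fracture signal", {
  # rims mirror across the midline; with noise sd well below the fracture
  # contrast their absolute difference stays under fractureContrast / 2
  geo <- OrbitCSL:::phantomGeometry(cfg64)
  rimR <- geo$rimR
  for (seed in 1:100) {
    p <- renderPhantom(seed, 0L, "none", cfg64)@pixels
    mirrored <- p[, ncol(p):1]
    expect_lt(max(abs(p[rimR] - mirrored[rimR])), cfg64@fractureContrast / 2)
  }
})

test_that("positive and negative renders differ only inside the declared fracture region", {
  for (site in c("floor", "medial", "superior", "lateral", "multiple")) {
    pos <- renderPhantom(21L, 1L, site, cfg64)@pixels
    neg <- renderPhantom(21L, 0L, "none", cfg64)@pixels
    msk <- fractureMask(site, cfg64)
    expect_identical(pos[!msk], neg[!msk])
    expect_gt(max(abs(pos[msk] - neg[msk])), cfg64@fractureContrast / 2)
  }
})

test_that("dataset generation honors exact counts, site probabilities and determinism", {
  cfg <- phantomConfig(nSamples = 100L, prevalence = 0.18, imageSize = 32L,
                       exactCounts = TRUE, seed = 5L)
  m <- generatePhantomDataset(cfg)
  expect_equal(sum(manifestRecords(m)$label), 18L)
  m2 <- generatePhantomDataset(cfg)
  expect_identical(manifestRecords(m), manifestRecords(m2))
  expect_identical(m@images, m2@images)
  expect_equal(unname(cfg@siteProbs["floor"]), 116 / 330, tolerance = 1e-12)
  # site draws follow siteProbs: with many positives the floor fraction is
  # within binomial noise of 35%
  big <- generatePhantomDataset(phantomConfig(nSamples = 400L,
                                              prevalence = 0.5,
                                              imageSize = 32L,
                                              exactCounts = TRUE, seed = 8L))
  rec <- manifestRecords(big)
  frac <- mean(rec$site[rec$label == 1L] == "floor")
  expect_lt(abs(frac - 116 / 330), 4 * sqrt(0.35 * 0.65 / 200))
  expect_error(generatePhantomDataset(phantomConfig(nSamples = 1L)), "at least 2")
})

test_that("ROI cropping returns the sub-grid and keeps the source label", {
  img <- matrix(runif(64 * 64), 64, 64)
  expect_equal(dim(cropRoi(img, c(8L, 8L, 56L, 56L))), c(48L, 48L))
  expect_identical(cropRoi(img, c(0L, 0L, 64L, 64L)), img)
  expect_error(cropRoi(img, c(0L, 0L, 65L, 64L)), "bounds")
  m <- tinyManifest(10L)
  rec <- manifestRecords(m)
  for (i in seq_len(nrow(rec))) {
    crop <- cropRoi(sampleImage(m, rec$sample_id[i]),
                    as.integer(rec[i, c("row_min", "col_min",
                                        "row_max", "col_max")]))
    expect_equal(dim(crop), c(rec$row_max[i] - rec$row_min[i],
                              rec$col_max[i] - rec$col_min[i]))
    # the crop is a view of the same sample; its label is the record label
    expect_true(rec$label[i] %in% c(0L, 1L))
  }
})

test_that("stratified split matches largest-remainder quotas and partitions the data", {
  cfg <- phantomConfig(nSamples = 20L, prevalence = 0.5, imageSize = 32L,
                       exactCounts = TRUE, seed = 2L)
  m <- splitDataset(generatePhantomDataset(cfg), c(7, 1, 2), seed = 4L)
  tab <- table(manifestRecords(m)$split, manifestRecords(m)$label)
  expect_equal(unname(tab["train", ]), c(7L, 7L))
  expect_equal(unname(tab["tune", ]), c(1L, 1L))
  expect_equal(unname(tab["test", ]), c(2L, 2L))
  # partition: every sample tagged exactly once
  expect_setequal(manifestRecords(m)$sample_id,
                  manifestRecords(generatePhantomDataset(cfg))$sample_id)
  expect_false(any(manifestRecords(m)$split == "unassigned"))
  # determinism
  m2 <- splitDataset(generatePhantomDataset(cfg), c(7, 1, 2), seed = 4L)
  expect_identical(manifestRecords(m), manifestRecords(m2))
  # degenerate ratio 1:0:1 on 4 samples of one class
  cfg4 <- phantomConfig(nSamples = 8L, prevalence = 0.5, imageSize = 32L,
                        exactCounts = TRUE, seed = 2L)
  m4 <- splitDataset(generatePhantomDataset(cfg4), c(1, 0, 1), seed = 1L)
  tab4 <- table(manifestRecords(m4)$split)
  expect_equal(as.integer(tab4[c("train", "test")]), c(4L, 4L))
  # tiny class -> warning, never silent
  cfgTiny <- phantomConfig(nSamples = 6L, prevalence = 0.2, imageSize = 32L,
                           exactCounts = TRUE, seed = 2L)
  expect_warning(splitDataset(generatePhantomDataset(cfgTiny), c(7, 1, 2)),
                 "fewer samples")
})

test_that("per-split positive fraction stays within one sample of the global fraction", {
  cfg <- phantomConfig(nSamples = 100L, prevalence = 0.18, imageSize = 32L,
                       exactCounts = TRUE, seed = 9L)
  m <- splitDataset(generatePhantomDataset(cfg), c(7, 1, 2), seed = 9L)
  rec <- manifestRecords(m)
  for (sp in c("train", "tune", "test")) {
    sub <- rec[rec$split == sp, ]
    expect_lt(abs(sum(sub$label) - 0.18 * nrow(sub)), 1 + 1e-9)
  }
})

test_that("negative subsampling balances train/tune only and is seeded", {
  cfg <- phantomConfig(nSamples = 120L, prevalence = 0.18, imageSize = 32L,
                       exactCounts = TRUE, seed = 6L)
  m <- splitDataset(generatePhantomDataset(cfg), c(7, 1, 2), seed = 6L)
  before <- manifestRecords(m)
  b <- subsampleNegatives(m, 1, seed = 3L)
  rec <- manifestRecords(b)
  for (sp in c("train", "tune")) {
    np <- sum(rec$split == sp & rec$label == 1L)
    nn <- sum(rec$split == sp & rec$label == 0L)
    expect_lte(nn, np)
  }
  afterTest <- rec[rec$split == "test", ]
  beforeTest <- before[before$split == "test", ]
  rownames(afterTest) <- rownames(beforeTest) <- NULL
  expect_identical(afterTest, beforeTest)
  b2 <- subsampleNegatives(m, 1, seed = 3L)
  expect_identical(rec$sample_id, manifestRecords(b2)$sample_id)
  expect_error(subsampleNegatives(m, 0), "negPosRatio")
  expect_error(subsampleNegatives(generatePhantomDataset(cfg), 1), "split tags")
})

test_that("datasets round-trip through PNG + manifest CSV", {
  dir <- withr::local_tempdir()
  m <- tinyManifest(6L, seed = 11L)
  out <- writeDataset(m, dir)
  expect_true(file.exists(file.path(dir, "manifest.csv")))
  back <- readDataset(dir)
  expect_identical(manifestRecords(back)$sample_id, manifestRecords(m)$sample_id)
  expect_identical(manifestRecords(back)$label, manifestRecords(m)$label)
  for (id in manifestRecords(m)$sample_id[1:3]) {
    a <- sampleImage(m, id); b <- sampleImage(back, id)
    rng <- range(a)
    # on-load min-max normalization rescales; compare on the common scale
    expect_equal(b * (rng[2] - rng[1]) + rng[1], a, tolerance = 2 / 255)
  }
})
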