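# Training drivers: reproducibility, loss conventions, pairing modes,
# cross-validation structure. All runs use the tiny profile.

test_that("training is reproducible from the seed", {
  m1 <- tinyTrainedModel("multi_csl", epochs = 2L, seed = 5L)
  m2 <- tinyTrainedModel("multi_csl", epochs = 2L, seed = 5L)
  expect_identical(trainingLog(m1), trainingLog(m2))
  expect_identical(m1@params, m2@params)
})

test_that("one epoch on a small set yields a finite logged loss and scores", {
  man <- splitDataset(tinyManifest(16L, seed = 3L), c(3, 1, 0), seed = 3L)
  model <- trainModel(man, trainConfig(epochs = 1L, mode = "multi", seed = 3L),
                      encOriginal = tinyEnc(3L))
  log <- trainingLog(model)
  expect_equal(nrow(log), 1L)
  expect_true(is.finite(log$loss))
  sc <- predictScores(model, man, "tune")
  expect_equal(nrow(sc), sum(manifestRecords(man)$split == "tune"))
  expect_true(all(sc$score >= 0 & sc$score <= 1))
})

test_that("mean-loss convention: a train set of duplicated samples logs the single-sample loss", {
  man <- splitDataset(tinyManifest(8L, seed = 5L), c(3, 1, 0), seed = 5L)
  rec <- manifestRecords(man)
  onePos <- rec$sample_id[rec$label == 1L & rec$split == "train"][1]
  oneNeg <- rec$sample_id[rec$label == 0L & rec$split == "train"][1]
  # freeze updates with a vanishing learning rate so the logged epoch loss
  # is the model's initial mean loss
  cfgT <- trainConfig(epochs = 1L, batchSize = 4L, learningRate = 1e-12,
                      mode = "multi", seed = 5L)
  dup <- man
  keep <- rec$sample_id %in% c(onePos, oneNeg) | rec$split != "train"
  dup@records <- rec[keep, , drop = FALSE]
  base <- trainModel(dup, cfgT, encOriginal = tinyEnc(5L))
  # duplicate the same two samples fourfold under fresh ids
  rec4 <- do.call(rbind, lapply(0:3, function(k) {
    r <- rec[rec$sample_id %in% c(onePos, oneNeg), , drop = FALSE]
    r$sample_id <- paste0(r$sample_id, "_d", k)
    r
  }))
  rec4 <- rbind(rec4, rec[rec$split != "train", , drop = FALSE])
  imgs <- lapply(rec4$sample_id, function(id)
    sampleImage(man, sub("_d[0-3]$", "", id)))
  names(imgs) <- rec4$sample_id
  man4 <- new("DatasetManifest", records = rec4, images = imgs,
              provenance = list())
  quad <- trainModel(man4, cfgT, encOriginal = tinyEnc(5L))
  expect_equal(trainingLog(quad)$loss, trainingLog(base)$loss,
               tolerance = 1e-8)
})

test_that("cross-sequence pairing is confined to training; evaluation is identity-paired", {
  model <- tinyTrainedModel("multi_csl", epochs = 1L, seed = 9L)
  expect_equal(model@provenance$planModes$train, "cross_sequence")
  expect_equal(model@provenance$planModes$tune, "identity")
  plan <- model@provenance$plan
  # training plan is a within-class permutation
  for (lab in unique(plan$label))
    expect_setequal(plan$crop_index[plan$label == lab],
                    plan$original_index[plan$label == lab])
  man <- splitDataset(tinyManifest(24L, seed = 9L), c(6, 1, 1), seed = 9L)
  csl <- planFromSimilarity(diag(4), c(1L, 1L, 0L, 0L))
  expect_error(predictScores(model, man, "test", plan = csl), "identity")
})

test_that("multi mode without cross-sequence learning trains on identity pairs", {
  model <- tinyTrainedModel("multi", epochs = 1L, seed = 4L)
  expect_equal(model@provenance$planModes$train, "identity")
  plan <- model@provenance$plan
  expect_equal(plan$crop_index, plan$original_index)
})

test_that("training errors on empty or single-class train splits", {
  man <- tinyManifest(12L, seed = 2L)
  expect_error(trainModel(man, trainConfig(epochs = 1L)), "empty train split")
  man2 <- splitDataset(man, c(3, 1, 0), seed = 2L)
  rec <- manifestRecords(man2)
  rec$split[rec$label == 1L & rec$split == "train"] <- "unassigned"
  man2@records <- rec
  expect_error(trainModel(man2, trainConfig(epochs = 1L)), "single class")
})

test_that("predict scores length, ordering invariance and single-branch isolation", {
  model <- tinyTrainedModel("single", epochs = 1L, seed = 6L)
  man <- splitDataset(tinyManifest(24L, seed = 6L), c(6, 1, 1), seed = 6L)
  sc <- predictScores(model, man, "test")
  expect_equal(nrow(sc), sum(manifestRecords(man)$split == "test"))
  # reorder the manifest records; per-sample scores must not change
  perm <- man
  idx <- withr::with_seed(1, sample(nrow(man@records)))
  perm@records <- man@records[idx, , drop = FALSE]
  sc2 <- predictScores(model, perm, "test")
  sc2 <- sc2[match(sc$sample_id, sc2$sample_id), ]
  expect_equal(sc$score, sc2$score)
  # single-mode scores are unchanged when every ROI is perturbed
  shifted <- man
  shifted@records$row_min <- pmax(0L, shifted@records$row_min - 2L)
  sc3 <- predictScores(model, shifted, "test")
  expect_equal(sc$score, sc3$score)
})

test_that("stratified cross-validation partitions samples and is seeded", {
  man <- tinyManifest(30L, seed = 8L, prevalence = 0.3)
  cfgT <- trainConfig(epochs = 1L, mode = "multi", seed = 8L)
  cv <- runCrossValidation(man, k = 3L, cfgT, encOriginal = tinyEnc(8L))
  allIds <- unlist(lapply(cv$folds, function(f) f$scores$sample_id))
  expect_setequal(allIds, manifestRecords(man)$sample_id)
  expect_equal(anyDuplicated(allIds), 0L)
  # stratification: each fold holds 3 of the 9 positives
  rec <- manifestRecords(man)
  for (f in cv$folds) {
    labs <- rec$label[match(f$scores$sample_id, rec$sample_id)]
    expect_equal(sum(labs), 3L)
  }
  fold1 <- OrbitCSL:::stratifiedFolds(rec$label, 3L, cfgT$seed)
  fold2 <- OrbitCSL:::stratifiedFolds(rec$label, 3L, cfgT$seed)
  expect_identical(fold1, fold2)
  expect_true(is.finite(cv$summary$pooledAuroc))
  expect_error(runCrossValidation(man, k = 12L, cfgT), "fewer than k")
  expect_error(runCrossValidation(man, k = 1L, cfgT), "k must be")
})
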