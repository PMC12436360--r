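# Training drivers: single-input, multi-input, and multi-input with
# cross-sequence pairing; 7:1:2 protocol support and stratified k-fold
# cross-validation. Optimization is decoupled-weight-decay Adam with a
# cosine learning-rate schedule on the mean binary cross-entropy.

#' Construct a training configuration
#'
#' @param epochs training epochs (desk default 40; use 400 to mirror a
#'   full-scale run).
#' @param batchSize minibatch size.
#' @param learningRate peak Adam learning rate (cosine-decayed to 0).
#' @param weightDecay decoupled weight decay on weight matrices.
#' @param mode `"multi_csl"` (cross-sequence pairing), `"multi"`
#'   (identity pairing), or `"single"` (originals only).
#' @param replanEachEpoch rebuild the cross-sequence plan every epoch
#'   instead of once per run.
#' @param similarityResolution resampling resolution for the raw-pixel
#'   similarity vectors.
#' @param negPosRatio balancing ratio used by [runCrossValidation()].
#' @param hFlip random horizontal flip augmentation (off by default).
#' @param seed master seed for initialization, data order and pairing.
#' @return validated configuration list.
#' @export
trainConfig <- function(epochs = 40L, batchSize = 8L, learningRate = 1e-3,
                        weightDecay = 1e-4,
                        mode = c("multi_csl", "multi", "single"),
                        replanEachEpoch = FALSE, similarityResolution = 64L,
                        negPosRatio = 1, hFlip = FALSE, seed = 1L) {
  mode <- match.arg(mode)
  stopifnot(epochs >= 1L, learningRate > 0, batchSize >= 1L,
            weightDecay >= 0, negPosRatio > 0)
  list(epochs = as.integer(epochs), batchSize = as.integer(batchSize),
       learningRate = learningRate, weightDecay = weightDecay, mode = mode,
       replanEachEpoch = isTRUE(replanEachEpoch),
       similarityResolution = as.integer(similarityResolution),
       negPosRatio = negPosRatio, hFlip = isTRUE(hFlip),
       seed = as.integer(seed))
}

# Raw images, crops, and per-branch patch matrices for a subset of samples.
prepareInputs <- function(manifest, idx, encO, encC) {
  rec <- manifest@records[idx, , drop = FALSE]
  orig <- lapply(rec$sample_id, function(id) sampleImage(manifest, id))
  crops <- lapply(seq_len(nrow(rec)), function(i)
    cropRoi(orig[[i]], as.integer(rec[i, c("row_min", "col_min",
                                           "row_max", "col_max")])))
  list(ids = rec$sample_id, labels = as.integer(rec$label),
       orig = orig, crops = crops,
       Xo = lapply(orig, function(m)
         patchify(resizeBilinear(m, encO@imageSize), encO@patchSize)),
       Xc = if (!is.null(encC)) lapply(crops, function(m)
         patchify(resizeBilinear(m, encC@imageSize), encC@patchSize)))
}

# Forward + loss + gradients for one (original, crop) pair.
pairGrad <- function(model, Xo, Xc, y) {
  fo <- encForward(model@params$origEnc, Xo, model@encOriginal)
  if (model@mode == "multi") {
    fc <- encForward(model@params$cropEnc, Xc, model@encCrop)
    feat <- c(fo$feat, fc$feat)
  } else feat <- fo$feat
  hf <- headForward(model@params$head, feat)
  z <- hf$logit
  loss <- max(z, 0) - z * y + log1p(exp(-abs(z)))
  hb <- headBackward(model@params$head, hf, sigmoid(z) - y)
  Do <- model@encOriginal@embedDim
  g <- list(origEnc = encBackward(model@params$origEnc, fo,
                                  hb$dfeat[seq_len(Do)],
                                  model@encOriginal)$grads)
  if (model@mode == "multi")
    g$cropEnc <- encBackward(model@params$cropEnc, fc,
                             hb$dfeat[-seq_len(Do)], model@encCrop)$grads
  g$head <- hb$grads
  list(loss = loss, grads = g, prob = sigmoid(z))
}

bceLoss <- function(scores, labels) {
  eps <- 1e-12
  -mean(labels * log(scores + eps) + (1 - labels) * log(1 - scores + eps))
}

scoresFromInputs <- function(model, inputs) {
  vapply(seq_along(inputs$ids), function(i) {
    fo <- encForward(model@params$origEnc, inputs$Xo[[i]], model@encOriginal)$feat
    f <- if (model@mode == "multi")
      c(fo, encForward(model@params$cropEnc, inputs$Xc[[i]], model@encCrop)$feat)
    else fo
    sigmoid(headForward(model@params$head, f)$logit)
  }, numeric(1))
}

#' Train a fusion classifier on a split-tagged manifest
#'
#' Minimizes mean binary cross-entropy on the train split. In
#' `"multi_csl"` mode every training input is the pair
#' (original_i, crop_j) given by the cross-sequence plan — both members
#' share the label — while tuning-set evaluation always uses identity
#' pairing: cross-sequence matching is a training-time device only. The
#' epoch with the best tuning AUROC supplies the returned parameters. Fully
#' reproducible from `config$seed`.
#'
#' @param manifest a split-tagged [DatasetManifest-class] (train and tune
#'   splits required; balance beforehand with [subsampleNegatives()]).
#' @param config a [trainConfig()].
#' @param encOriginal,encCrop branch architecture configurations.
#' @param hiddenDim classification-head hidden width.
#' @return a trained [FusionClassifier-class]; `trainingLog(model)` holds
#'   per-epoch loss and tuning AUROC, and `model@provenance$planModes`
#'   records the pairing mode seen in each phase.
#' @export
trainModel <- function(manifest, config = trainConfig(),
                       encOriginal = deskProfile(seed = config$seed),
                       encCrop = encOriginal, hiddenDim = 64L) {
  rec <- manifest@records
  trainIdx <- which(rec$split == "train")
  tuneIdx <- which(rec$split == "tune")
  if (!length(trainIdx)) stop("empty train split", call. = FALSE)
  if (length(unique(rec$label[trainIdx])) < 2L)
    stop("train split contains a single class", call. = FALSE)
  modelMode <- if (config$mode == "single") "single" else "multi"
  model <- buildFusionClassifier(modelMode, encOriginal, encCrop,
                                 hiddenDim, seed = config$seed)
  encC <- if (modelMode == "multi") encCrop else NULL
  tr <- prepareInputs(manifest, trainIdx, encOriginal, encC)
  tu <- if (length(tuneIdx)) prepareInputs(manifest, tuneIdx, encOriginal, encC)

  buildPlan <- function() {
    if (config$mode == "multi_csl")
      buildCrossSequencePlan(tr$orig, tr$crops, tr$labels,
                             config$similarityResolution)
    else identityPlan(length(tr$ids), tr$labels)
  }
  plan <- buildPlan()

  mState <- zeroLike(model@params); vState <- zeroLike(model@params)
  n <- length(tr$ids)
  log <- data.frame(epoch = integer(), loss = numeric(),
                    tune_auroc = numeric(), tune_loss = numeric(),
                    lr = numeric())
  best <- list(auroc = -Inf, loss = Inf, params = model@params, epoch = 0L)
  step <- 0L
  for (epoch in seq_len(config$epochs)) {
    if (config$replanEachEpoch && epoch > 1L) plan <- buildPlan()
    lrE <- config$learningRate *
      0.5 * (1 + cos(pi * (epoch - 1) / config$epochs))
    order <- withSeed(config$seed + 7L * epoch, sample.int(n))
    epochLoss <- 0
    cropOf <- plan@pairs$crop_index[order(plan@pairs$original_index)]
    for (start in seq(1L, n, by = config$batchSize)) {
      batch <- order[start:min(start + config$batchSize - 1L, n)]
      gsum <- NULL; bloss <- 0
      for (i in batch) {
        Xo <- tr$Xo[[i]]
        Xc <- if (modelMode == "multi") tr$Xc[[cropOf[i]]]
        if (config$hFlip) {
          flip <- withSeed(config$seed + 13L * epoch + i,
                           runif(2) < 0.5)
          if (flip[1]) Xo <- patchify(
            resizeBilinear(tr$orig[[i]], encOriginal@imageSize)[,
              encOriginal@imageSize:1], encOriginal@patchSize)
          if (!is.null(Xc) && flip[2]) Xc <- patchify(
            resizeBilinear(tr$crops[[cropOf[i]]], encCrop@imageSize)[,
              encCrop@imageSize:1], encCrop@patchSize)
        }
        pg <- pairGrad(model, Xo, Xc, tr$labels[i])
        bloss <- bloss + pg$loss
        gsum <- if (is.null(gsum)) pg$grads else addTrees(gsum, pg$grads)
      }
      gmean <- scaleTree(gsum, 1 / length(batch))
      step <- step + 1L
      upd <- adamStep(model@params, gmean, mState, vState, step, lrE,
                      config$weightDecay)
      model@params <- upd$p; mState <- upd$m; vState <- upd$v
      epochLoss <- epochLoss + bloss
    }
    tuneAuc <- NA_real_; tuneLoss <- NA_real_
    if (length(tuneIdx)) {
      ts <- scoresFromInputs(model, tu)
      tuneLoss <- bceLoss(ts, tu$labels)
      if (length(unique(tu$labels)) == 2L) tuneAuc <- auroc(ts, tu$labels)
    }
    log <- rbind(log, data.frame(epoch = epoch, loss = epochLoss / n,
                                 tune_auroc = tuneAuc, tune_loss = tuneLoss,
                                 lr = lrE))
    # model selection: best tuning AUROC, ties broken by lower tuning loss
    # (the small tuning split saturates AUROC early)
    if (!is.na(tuneAuc) &&
        (tuneAuc > best$auroc ||
         (tuneAuc == best$auroc && tuneLoss < best$loss)))
      best <- list(auroc = tuneAuc, loss = tuneLoss,
                   params = model@params, epoch = epoch)
  }
  if (best$epoch > 0L) model@params <- best$params
  model@trainingLog <- log
  model@provenance <- list(
    trainConfig = config, bestEpoch = best$epoch,
    planModes = list(train = plan@mode, tune = "identity"),
    plan = plan@pairs, nTrain = n, nTune = length(tuneIdx))
  model
}

#' Score a manifest subset with identity pairing
#'
#' One probability per sample, deterministic given the parameters.
#' Evaluation always pairs each original with its own crop; a
#' cross-sequence plan is rejected here.
#'
#' @param model a trained [FusionClassifier-class].
#' @param manifest a [DatasetManifest-class].
#' @param split which split to score (default `"test"`).
#' @param plan optional [MatchingPlan-class]; must be identity mode and
#'   match the subset length.
#' @return data.frame with columns sample_id, score, label.
#' @export
predictScores <- function(model, manifest, split = "test", plan = NULL) {
  idx <- which(manifest@records$split == split)
  if (!length(idx)) stop("no samples in split '", split, "'", call. = FALSE)
  inputs <- prepareInputs(manifest, idx, model@encOriginal,
                          if (model@mode == "multi") model@encCrop)
  if (is.null(plan)) plan <- identityPlan(length(idx), inputs$labels)
  if (plan@mode != "identity")
    stop("evaluation requires an identity plan", call. = FALSE)
  if (nrow(plan@pairs) != length(idx))
    stop("plan and manifest subset differ in length", call. = FALSE)
  data.frame(sample_id = inputs$ids,
             score = scoresFromInputs(model, inputs),
             label = inputs$labels, stringsAsFactors = FALSE)
}

# Manifest restricted to `idx`, with images subset alongside the records.
subsetManifest <- function(manifest, idx, split = NULL) {
  rec <- manifest@records[idx, , drop = FALSE]
  if (!is.null(split)) rec$split <- split
  rownames(rec) <- NULL
  imgs <- if (length(manifest@images))
    manifest@images[intersect(rec$sample_id, names(manifest@images))]
  else list()
  new("DatasetManifest", records = rec, images = imgs,
      provenance = manifest@provenance)
}

# Stratified fold ids: per class, shuffle then deal round-robin.
stratifiedFolds <- function(labels, k, seed) {
  fold <- integer(length(labels))
  for (lab in unique(labels)) {
    idx <- which(labels == lab)
    if (length(idx) < k)
      stop("label class ", lab, " has fewer than k = ", k, " members",
           call. = FALSE)
    ord <- withSeed(seed + as.integer(lab), sample(idx))
    fold[ord] <- rep_len(seq_len(k), length(ord))
  }
  fold
}

#' Stratified k-fold cross-validation
#'
#' Every sample appears in exactly one test fold; within each fold the
#' remaining samples are split 7:1 into train and tune sets, negatives are
#' balanced at `config$negPosRatio`, and a model is trained and scored on
#' the held-out fold. The summary reports both the pooled-score AUROC and
#' the mean +/- sd of per-fold AUROCs (the two ways of combining folds).
#'
#' @param manifest a [DatasetManifest-class] (split tags are ignored;
#'   folding is done here).
#' @param k number of folds (>= 2; every class must have >= k members).
#' @param config a [trainConfig()].
#' @param encOriginal,encCrop,hiddenDim passed to [trainModel()].
#' @return list with `folds` (per-fold scores and AUROC) and `summary`
#'   (pooled scores, pooled AUROC, mean and sd of fold AUROCs).
#' @export
runCrossValidation <- function(manifest, k = 10L, config = trainConfig(),
                               encOriginal = deskProfile(seed = config$seed),
                               encCrop = encOriginal, hiddenDim = 64L) {
  k <- as.integer(k)
  if (k < 2L) stop("k must be >= 2", call. = FALSE)
  rec <- manifest@records
  fold <- stratifiedFolds(rec$label, k, config$seed)
  folds <- vector("list", k)
  for (f in seq_len(k)) {
    inner <- subsetManifest(manifest, which(fold != f), split = "unassigned")
    inner <- splitDataset(inner, c(7, 1, 0), seed = config$seed + 100L + f)
    inner <- subsampleNegatives(inner, config$negPosRatio,
                                seed = config$seed + 200L + f)
    testM <- subsetManifest(manifest, which(fold == f), split = "test")
    inner@records <- rbind(inner@records, testM@records)
    rownames(inner@records) <- NULL
    inner@images <- c(inner@images, testM@images)
    model <- trainModel(inner, config, encOriginal, encCrop, hiddenDim)
    sc <- predictScores(model, inner, "test")
    aucF <- if (length(unique(sc$label)) == 2L) auroc(sc$score, sc$label)
            else NA_real_
    folds[[f]] <- list(foldIndex = f, scores = sc, auroc = aucF,
                       bestEpoch = model@provenance$bestEpoch)
  }
  pooled <- do.call(rbind, lapply(folds, `[[`, "scores"))
  aucs <- vapply(folds, `[[`, numeric(1), "auroc")
  list(folds = folds,
       summary = list(pooledScores = pooled,
                      pooledAuroc = auroc(pooled$score, pooled$label),
                      foldAurocMean = mean(aucs, na.rm = TRUE),
                      foldAurocSd = sd(aucs, na.rm = TRUE)))
}
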