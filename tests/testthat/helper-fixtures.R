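# Shared fixtures and independent oracles for the suite.

# Small encoder/train settings so unit tests stay fast.
tinyEnc <- function(seed = 1L)
  encoderConfig(imageSize = 16L, patchSize = 4L, embedDim = 16L, depth = 2L,
                nHeads = 2L, mlpRatio = 2, seed = seed)

tinyManifest <- function(n = 24L, seed = 7L, contrast = 0.7,
                         prevalence = 0.5) {
  cfg <- phantomConfig(nSamples = n, prevalence = prevalence,
                       imageSize = 32L, fractureContrast = contrast,
                       exactCounts = TRUE, seed = seed)
  generatePhantomDataset(cfg)
}

tinyTrainedModel <- function(mode = "multi", n = 24L, epochs = 2L,
                             seed = 7L) {
  m <- splitDataset(tinyManifest(n, seed), c(6, 1, 1), seed = seed)
  trainModel(m, trainConfig(epochs = epochs, mode = mode, seed = seed),
             encOriginal = tinyEnc(seed))
}

# Independent trapezoidal ROC area: sweep thresholds high to low and sum
# trapezoids in (FPR, TPR) space.
trapezoidAuroc <- function(scores, labels) {
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE))
  nPos <- sum(labels == 1); nNeg <- sum(labels == 0)
  tpr <- vapply(thr, function(t) sum(scores >= t & labels == 1) / nPos,
                numeric(1))
  fpr <- vapply(thr, function(t) sum(scores >= t & labels == 0) / nNeg,
                numeric(1))
  sum(diff(fpr) * (head(tpr, -1) + tail(tpr, -1)) / 2)
}

# Step-by-step re-simulation of the greedy lowest-similarity matching rule,
# written against the raw vectors (its own cosine, pool bookkeeping via a
# candidate set) rather than the package's matrix formulation.
greedyMatchOracle <- function(vo, vc, labels) {
  n <- nrow(vo)
  cosim <- function(a, b) sum(a * b) / sqrt(sum(a^2) * sum(b^2))
  pool <- seq_len(n)
  out <- integer(n)
  for (i in seq_len(n)) {
    cand <- pool[labels[pool] == labels[i]]
    if (length(cand) > 1 || (length(cand) == 1 && cand != i))
      cand <- cand[cand != i]
    sims <- vapply(cand, function(j) cosim(vo[i, ], vc[j, ]), numeric(1))
    pick <- cand[order(sims, cand)[1]]
    out[i] <- pick
    pool <- setdiff(pool, pick)
  }
  out
}

# Exhaustive Youden search: every observed threshold, tie to the lowest.
youdenOracle <- function(scores, labels) {
  best <- list(J = -Inf, thr = NA)
  for (t in sort(unique(scores))) {
    sens <- mean(scores[labels == 1] >= t)
    spec <- mean(scores[labels == 0] < t)
    if (sens + spec - 1 > best$J + 1e-12)
      best <- list(J = sens + spec - 1, thr = t)
  }
  best
}

# Sign-flip permutation test for the paired AUC difference: under the null
# the labels of the two score sets are exchangeable per case.
delongPermutationOracle <- function(sa, sb, labels, nPerm = 20000L,
                                    seed = 1L) {
  obs <- abs(auroc(sa, labels) - auroc(sb, labels))
  withr::with_seed(seed, {
    hits <- 0L
    for (i in seq_len(nPerm)) {
      flip <- runif(length(sa)) < 0.5
      a <- ifelse(flip, sb, sa); b <- ifelse(flip, sa, sb)
      if (abs(auroc(a, labels) - auroc(b, labels)) >= obs - 1e-12)
        hits <- hits + 1L
    }
    (hits + 1) / (nPerm + 1)
  })
}

# Patch-grid downsample of a pixel mask: TRUE where any pixel of the patch
# is set.
maskToPatches <- function(mask, grid = 8L) {
  ps <- nrow(mask) %/% grid
  out <- matrix(FALSE, grid, grid)
  for (r in seq_len(grid)) for (cc in seq_len(grid))
    out[r, cc] <- any(mask[((r - 1L) * ps + 1L):(r * ps),
                           ((cc - 1L) * ps + 1L):(cc * ps)])
  out
}

# Table of two-session reader confusion counts (tp, fp, fn, tn) implied by
# the printed sensitivities/specificities of a 31-fracture / 110-normal
# test set; used by the reader-study and acceptance tests.
readerCountsFixture <- function() {
  list(
    r1 = list(unassisted = c(13L, 21L, 18L, 89L),
              assisted   = c(10L, 10L, 21L, 100L)),
    r2 = list(unassisted = c(12L, 30L, 19L, 80L),
              assisted   = c(13L, 12L, 18L, 98L)),
    r3 = list(unassisted = c(20L, 40L, 11L, 70L),
              assisted   = c(16L, 30L, 15L, 80L)))
}
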