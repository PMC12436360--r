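#' @import methods
#' @importFrom stats rnorm rbinom runif pnorm dnorm qbeta pbinom pchisq sd var
#' @importFrom utils read.csv write.csv head
NULL

SITE_LEVELS <- c("none", "floor", "medial", "superior", "lateral", "multiple")
SPLIT_LEVELS <- c("train", "tune", "test", "unassigned")

#' Configuration for the orbital-radiograph phantom generator
#'
#' Holds every tunable of the synthetic phantom study: cohort size, fracture
#' prevalence, the distribution of fracture sites among positives, image
#' geometry and the strength of the fracture signal relative to the noise
#' floor.
#'
#' @slot nSamples integer, number of phantoms to generate.
#' @slot prevalence fracture prevalence in (0,1); default 0.18, the rate in
#'   the pediatric facial-trauma population the generator emulates.
#' @slot siteProbs named probability vector over fracture sites
#'   (floor, medial, superior, lateral, multiple); must sum to 1.
#' @slot imageSize side length of the square phantom in pixels.
#' @slot fractureContrast amplitude (intensity units, image scale [0,1]) of
#'   the rim discontinuity drawn for positive phantoms.
#' @slot noiseSd standard deviation of the additive Gaussian noise layer.
#' @slot exactCounts logical; if TRUE the number of positives is exactly
#'   `round(nSamples * prevalence)` instead of binomial.
#' @slot roiTightness `"head"` (ROI = head bounding box) or `"orbit"`
#'   (tight box around the two orbital rims).
#' @slot seed integer master seed; all per-sample seeds derive from it.
#' @export
setClass("PhantomConfig",
  representation(
    nSamples = "integer", prevalence = "numeric", siteProbs = "numeric",
    imageSize = "integer", fractureContrast = "numeric", noiseSd = "numeric",
    exactCounts = "logical", roiTightness = "character", seed = "integer"
  )
)

setValidity("PhantomConfig", function(object) {
  msg <- character()
  if (length(object@nSamples) != 1L || is.na(object@nSamples) || object@nSamples < 1L)
    msg <- c(msg, "nSamples must be a positive integer")
  if (object@prevalence <= 0 || object@prevalence >= 1)
    msg <- c(msg, "prevalence must lie in (0, 1)")
  if (length(object@siteProbs) != 5L ||
      !identical(names(object@siteProbs), SITE_LEVELS[-1]))
    msg <- c(msg, "siteProbs must be named (floor, medial, superior, lateral, multiple)")
  else if (abs(sum(object@siteProbs) - 1) > 1e-9 || any(object@siteProbs < 0))
    msg <- c(msg, "siteProbs must be non-negative and sum to 1 within 1e-9")
  if (object@imageSize < 16L)
    msg <- c(msg, "imageSize must be a positive integer >= 16")
  if (object@fractureContrast <= 0) msg <- c(msg, "fractureContrast must be > 0")
  if (object@noiseSd < 0) msg <- c(msg, "noiseSd must be >= 0")
  if (!object@roiTightness %in% c("head", "orbit"))
    msg <- c(msg, "roiTightness must be 'head' or 'orbit'")
  if (length(msg)) msg else TRUE
})

#' One synthetic radiograph with ground truth
#'
#' A single grayscale phantom: the pixel grid, the binary fracture label, the
#' region-of-interest (ROI) box and, for positives, the fracture site.
#' Boxes are 0-based, half-open `(row_min, col_min, row_max, col_max)`;
#' this convention is used for every box in the package.
#'
#' @slot sampleId character scalar, unique within a dataset.
#' @slot pixels numeric matrix (rows x cols), intensities in [0,1].
#' @slot label integer 0 (normal) or 1 (fracture).
#' @slot roi integer(4), 0-based half-open box.
#' @slot site one of none, floor, medial, superior, lateral, multiple;
#'   `none` if and only if `label == 0`.
#' @slot seed integer seed that produced the noise layer.
#' @export
setClass("RadiographSample",
  representation(
    sampleId = "character", pixels = "matrix", label = "integer",
    roi = "integer", site = "character", seed = "integer"
  )
)

setValidity("RadiographSample", function(object) {
  msg <- character()
  p <- object@pixels
  if (!is.numeric(p) || length(dim(p)) != 2L)
    msg <- c(msg, "pixels must be a numeric matrix")
  else {
    if (any(!is.finite(p)) || any(p < 0) || any(p > 1))
      msg <- c(msg, "all intensities must be finite and within [0,1]")
    r <- object@roi
    if (length(r) != 4L || r[1] < 0L || r[2] < 0L ||
        r[1] >= r[3] || r[2] >= r[4] || r[3] > nrow(p) || r[4] > ncol(p))
      msg <- c(msg, "roi must satisfy 0 <= min < max <= image extent")
  }
  if (!object@label %in% c(0L, 1L)) msg <- c(msg, "label must be 0 or 1")
  if (!object@site %in% SITE_LEVELS) msg <- c(msg, "unknown fracture site")
  if ((object@site == "none") != (object@label == 0L))
    msg <- c(msg, "site must be 'none' if and only if label is 0")
  if (length(msg)) msg else TRUE
})

#' Dataset manifest
#'
#' Table of samples (id, path, label, ROI, site, split tag) plus the in-memory
#' pixel grids and the generating provenance (config and seed), so a dataset
#' is fully reproducible and can be materialized to PNG + CSV on demand.
#'
#' @slot records data.frame with columns sample_id, path, label, row_min,
#'   col_min, row_max, col_max, site, split.
#' @slot images named list of pixel matrices keyed by sample_id (possibly
#'   empty when the dataset lives on disk).
#' @slot provenance list carrying the generating config and seeds.
#' @export
setClass("DatasetManifest",
  representation(records = "data.frame", images = "list", provenance = "list")
)

setValidity("DatasetManifest", function(object) {
  msg <- character()
  need <- c("sample_id", "path", "label", "row_min", "col_min", "row_max",
            "col_max", "site", "split")
  if (!all(need %in% names(object@records)))
    msg <- c(msg, paste("records must have columns:", paste(need, collapse = ", ")))
  else {
    if (anyDuplicated(object@records$sample_id))
      msg <- c(msg, "sample_ids must be unique")
    if (!all(object@records$split %in% SPLIT_LEVELS))
      msg <- c(msg, "split tags must be train/tune/test/unassigned")
    if (!all(object@records$label %in% c(0L, 1L)))
      msg <- c(msg, "labels must be 0/1")
  }
  if (length(object@images) &&
      !all(names(object@images) %in% object@records$sample_id))
    msg <- c(msg, "images must be keyed by manifest sample_ids")
  if (length(msg)) msg else TRUE
})

#' Cross-sequence matching plan
#'
#' The list of (original, crop) index pairs produced either by cross-sequence
#' matching (training) or identity pairing (validation/test). Within each
#' label class the crop indices are a permutation of the original indices:
#' every original is paired exactly once and no crop is reused.
#'
#' @slot pairs data.frame with columns original_index, crop_index (1-based),
#'   label, similarity.
#' @slot mode `"cross_sequence"` or `"identity"`.
#' @slot provenance list (similarity resolution, processing order, seed).
#' @export
setClass("MatchingPlan",
  representation(pairs = "data.frame", mode = "character", provenance = "list")
)

setValidity("MatchingPlan", function(object) {
  msg <- character()
  p <- object@pairs
  need <- c("original_index", "crop_index", "label", "similarity")
  if (!all(need %in% names(p)))
    msg <- c(msg, paste("pairs must have columns:", paste(need, collapse = ", ")))
  else if (nrow(p)) {
    if (anyDuplicated(p$original_index) || anyDuplicated(p$crop_index))
      msg <- c(msg, "each original_index and crop_index must appear exactly once")
    if (any(p$original_index < 1L) || any(p$crop_index < 1L))
      msg <- c(msg, "indices are 1-based positive integers")
    for (lab in unique(p$label)) {
      sel <- p$label == lab
      if (!setequal(p$original_index[sel], p$crop_index[sel]))
        msg <- c(msg, "within each label class the map must be a permutation")
    }
    if (any(!is.na(p$similarity) & (p$similarity < -1 - 1e-12 | p$similarity > 1 + 1e-12)))
      msg <- c(msg, "similarities must lie in [-1, 1]")
  }
  if (!object@mode %in% c("cross_sequence", "identity"))
    msg <- c(msg, "mode must be cross_sequence or identity")
  if (length(msg)) msg else TRUE
})

#' Transformer-encoder configuration
#'
#' Architecture hyperparameters of one vision-transformer branch: input side
#' length, patch size, embedding width, depth (number of pre-norm
#' attention + MLP blocks), number of attention heads, MLP expansion ratio,
#' dropout rate and the initialization seed.
#'
#' @export
setClass("EncoderConfig",
  representation(
    imageSize = "integer", patchSize = "integer", embedDim = "integer",
    depth = "integer", nHeads = "integer", mlpRatio = "numeric",
    dropout = "numeric", seed = "integer"
  )
)

setValidity("EncoderConfig", function(object) {
  msg <- character()
  if (object@imageSize %% object@patchSize != 0L)
    msg <- c(msg, "imageSize must be divisible by patchSize")
  if (object@embedDim %% object@nHeads != 0L)
    msg <- c(msg, "embedDim must be divisible by nHeads")
  if (object@depth < 1L) msg <- c(msg, "depth must be >= 1")
  if (object@dropout < 0 || object@dropout >= 1)
    msg <- c(msg, "dropout must lie in [0, 1)")
  if (object@mlpRatio <= 0) msg <- c(msg, "mlpRatio must be > 0")
  if (length(msg)) msg else TRUE
})

#' Dual-branch fusion classifier
#'
#' Two parallel transformer encoders — one over the original image, one over
#' the ROI crop — whose classification-token features are concatenated and
#' passed through a fully connected head ending in a single fracture logit.
#' In `"single"` mode only the original-image branch exists.
#'
#' @slot mode `"single"` or `"multi"`.
#' @slot encOriginal,encCrop branch configurations (`encCrop` unused in
#'   single mode).
#' @slot params nested list of parameter matrices (encoders + head).
#' @slot hiddenDim width of the hidden fully connected layer.
#' @slot trainingLog data.frame of per-epoch loss and tuning AUROC (empty
#'   for an untrained model).
#' @slot provenance list (training config, plan provenance, best epoch).
#' @export
setClass("FusionClassifier",
  representation(
    mode = "character", encOriginal = "EncoderConfig", encCrop = "EncoderConfig",
    params = "list", hiddenDim = "integer", trainingLog = "data.frame",
    provenance = "list"
  )
)

setValidity("FusionClassifier", function(object) {
  if (!object@mode %in% c("single", "multi"))
    return("mode must be 'single' or 'multi'")
  TRUE
})

#' Confusion-matrix counts
#'
#' @slot tp,fp,fn,tn non-negative integer counts.
#' @export
setClass("ConfusionCounts",
  representation(tp = "integer", fp = "integer", fn = "integer", tn = "integer")
)

setValidity("ConfusionCounts", function(object) {
  v <- c(object@tp, object@fp, object@fn, object@tn)
  if (any(is.na(v)) || any(v < 0L)) return("counts must be non-negative integers")
  if (sum(v) == 0L) return("all-zero confusion matrix")
  TRUE
})

#' Saliency map from gradient-weighted class activation mapping
#'
#' @slot grid non-negative matrix at patch-grid resolution (max 1 after
#'   normalization unless all activations vanish, in which case the map is
#'   all-zero and `degenerate` is TRUE).
#' @slot map bilinear upsample of `grid` at image resolution.
#' @slot sampleId source sample id.
#' @slot score model fracture probability for the sample.
#' @slot degenerate TRUE when every gradient was zero.
#' @export
setClass("SaliencyMap",
  representation(grid = "matrix", map = "matrix", sampleId = "character",
                 score = "numeric", degenerate = "logical")
)

setValidity("SaliencyMap", function(object) {
  if (any(object@grid < 0)) return("saliency values must be non-negative")
  if (!object@degenerate && nrow(object@grid) &&
      abs(max(object@grid) - 1) > 1e-8)
    return("normalized map must have maximum 1")
  TRUE
})
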