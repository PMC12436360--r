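# User-facing model surface: branch configurations, the dual-branch fusion
# classifier, and the single-sample forward primitives.

#' Construct a transformer-encoder configuration
#'
#' @param imageSize input side length (images are resized upstream).
#' @param patchSize patch side; must divide `imageSize`.
#' @param embedDim token embedding width; must be divisible by `nHeads`.
#' @param depth number of attention + MLP blocks.
#' @param nHeads number of self-attention heads.
#' @param mlpRatio hidden-width multiplier of the block MLP.
#' @param dropout residual-branch dropout probability in [0,1).
#' @param seed initialization seed.
#' @return an [EncoderConfig-class].
#' @export
encoderConfig <- function(imageSize = 64L, patchSize = 8L, embedDim = 48L,
                          depth = 2L, nHeads = 4L, mlpRatio = 2,
                          dropout = 0, seed = 1L) {
  new("EncoderConfig", imageSize = as.integer(imageSize),
      patchSize = as.integer(patchSize), embedDim = as.integer(embedDim),
      depth = as.integer(depth), nHeads = as.integer(nHeads),
      mlpRatio = mlpRatio, dropout = dropout, seed = as.integer(seed))
}

#' Built-in architecture profiles
#'
#' `deskProfile` is a compact encoder (64-pixel input, 8-pixel patches,
#' width 48, depth 2, 4 heads) sized so that a from-scratch model trains
#' reliably on CPU-scale phantom studies; `fullProfile` is a conventional
#' small ViT (224-pixel input, 16-pixel patches, width 192, depth 12,
#' 3 heads) for full-scale runs.
#'
#' @param seed initialization seed.
#' @return an [EncoderConfig-class].
#' @export
deskProfile <- function(seed = 1L)
  encoderConfig(imageSize = 64L, patchSize = 8L, embedDim = 48L, depth = 2L,
                nHeads = 4L, mlpRatio = 2, seed = seed)

#' @rdname deskProfile
#' @export
fullProfile <- function(seed = 1L)
  encoderConfig(imageSize = 224L, patchSize = 16L, embedDim = 192L,
                depth = 12L, nHeads = 3L, mlpRatio = 4, seed = seed)

#' Build an untrained fusion classifier
#'
#' In `"multi"` mode two parallel encoders process the original image and
#' the ROI crop and their classification-token features are concatenated —
#' there is no other fusion machinery — before a fully connected head (one
#' hidden rectified layer, then a single logit). `"single"` mode keeps only
#' the original-image branch.
#'
#' @param mode `"single"` or `"multi"`.
#' @param encOriginal,encCrop branch configurations.
#' @param hiddenDim hidden width of the classification head.
#' @param seed head-initialization seed.
#' @return a [FusionClassifier-class].
#' @export
buildFusionClassifier <- function(mode = c("multi", "single"),
                                  encOriginal = deskProfile(),
                                  encCrop = encOriginal,
                                  hiddenDim = 64L, seed = 1L) {
  mode <- match.arg(mode)
  fdim <- if (mode == "multi") encOriginal@embedDim + encCrop@embedDim
          else encOriginal@embedDim
  params <- list(origEnc = initEncoder(encOriginal))
  if (mode == "multi")
    params$cropEnc <- initEncoder(
      encoderConfig(encCrop@imageSize, encCrop@patchSize, encCrop@embedDim,
                    encCrop@depth, encCrop@nHeads, encCrop@mlpRatio,
                    encCrop@dropout, seed = encCrop@seed + 1L))
  params$head <- initHead(fdim, as.integer(hiddenDim), seed + 2L)
  new("FusionClassifier", mode = mode, encOriginal = encOriginal,
      encCrop = encCrop, params = params, hiddenDim = as.integer(hiddenDim),
      trainingLog = data.frame(), provenance = list())
}

#' Encode one image with a transformer branch
#'
#' Resizes to the configured input size, patchifies, and runs the encoder
#' forward pass; returns the classification-token feature vector. With
#' dropout disabled (the default) the output is a deterministic function of
#' the parameters and the image.
#'
#' @param image numeric matrix in [0,1].
#' @param config an [EncoderConfig-class].
#' @param params encoder parameter tree (from a built model).
#' @return numeric feature vector of length `config@embedDim`.
#' @export
encodeImage <- function(image, config, params) {
  img <- resizeBilinear(image, config@imageSize, config@imageSize)
  encForward(params, patchify(img, config@patchSize), config)$feat
}

#' Concatenate two branch feature vectors
#'
#' Fusion is sequential concatenation (`a` then `b`); order is preserved.
#'
#' @param a,b non-empty finite numeric vectors.
#' @return numeric vector of length `length(a) + length(b)`.
#' @export
fuseFeatures <- function(a, b) {
  if (!length(a) || !length(b))
    stop("cannot fuse an empty feature vector", call. = FALSE)
  if (any(!is.finite(a)) || any(!is.finite(b)))
    stop("feature vectors must be finite", call. = FALSE)
  c(a, b)
}

#' Classify a fused feature vector
#'
#' Fully connected head then the logistic transform; returns the fracture
#' probability.
#'
#' @param fused feature vector; length must equal the head input width.
#' @param headParams head parameter list.
#' @return probability in [0,1].
#' @export
classifyFused <- function(fused, headParams) {
  if (length(fused) != nrow(headParams$Wh))
    stop("fused vector length ", length(fused),
         " does not match head input width ", nrow(headParams$Wh),
         call. = FALSE)
  sigmoid(headForward(headParams, fused)$logit)
}

#' Fracture probability for one (original, crop) input
#'
#' @param model a [FusionClassifier-class].
#' @param original original-image matrix.
#' @param crop ROI-crop matrix (ignored in single mode).
#' @return probability in [0,1].
#' @export
predictProb <- function(model, original, crop = NULL) {
  fo <- encodeImage(original, model@encOriginal, model@params$origEnc)
  f <- if (model@mode == "multi") {
    if (is.null(crop)) stop("multi mode requires a crop input", call. = FALSE)
    fuseFeatures(fo, encodeImage(crop, model@encCrop, model@params$cropEnc))
  } else fo
  classifyFused(f, model@params$head)
}

#' Total trainable parameter count
#'
#' @param model a [FusionClassifier-class].
#' @return integer count over all encoder and head parameters.
#' @export
countParams <- function(model) as.integer(countLeaves(model@params))

#' @rdname manifestRecords
#' @param model a [FusionClassifier-class].
#' @export
trainingLog <- function(model) model@trainingLog

setMethod("show", "FusionClassifier", function(object) {
  cat("FusionClassifier [", object@mode, "] ", countParams(object),
      " parameters\n", sep = "")
  co <- object@encOriginal
  cat("  original branch: image", co@imageSize, "patch", co@patchSize,
      "embed", co@embedDim, "depth", co@depth, "heads", co@nHeads, "\n")
  if (object@mode == "multi") {
    cc <- object@encCrop
    cat("  crop branch:     image", cc@imageSize, "patch", cc@patchSize,
        "embed", cc@embedDim, "depth", cc@depth, "heads", cc@nHeads, "\n")
  }
  if (nrow(object@trainingLog)) {
    best <- object@provenance$bestEpoch
    cat("  trained", nrow(object@trainingLog), "epochs; best tune AUROC",
        sprintf("%.3f", max(object@trainingLog$tune_auroc)),
        if (!is.null(best)) paste0("(epoch ", best, ")"), "\n")
  }
  invisible(NULL)
})
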