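# Cross-sequence learning, steps 1-2: pair every original image with the
# same-label ROI crop of lowest raw-pixel cosine similarity, without
# replacement; identity pairing for validation/test.

#' Flatten an image to a fixed-length raw-pixel similarity vector
#'
#' Originals and crops have different shapes, so both are resampled to a
#' common `resolution x resolution` grid by bilinear interpolation and then
#' flattened row-major. No standardization is applied: the similarity is
#' computed on raw pixel values.
#'
#' @param image numeric matrix.
#' @param resolution side length of the similarity grid (default 64).
#' @return numeric vector of length `resolution^2`.
#' @export
flattenForSimilarity <- function(image, resolution = 64L) {
  stopIfNot01Matrix(image)
  stopifnot(resolution >= 1L)
  as.vector(t(resizeBilinear(image, resolution, resolution)))
}

#' Cosine similarity of two vectors
#'
#' `u . v / (|u| |v|)`, clamped to [-1, 1] against rounding. Zero-norm input
#' is a degenerate-input error, never a silent 0.
#'
#' @param u,v numeric vectors of equal length.
#' @return similarity in [-1, 1].
#' @export
cosineSimilarity <- function(u, v) {
  if (length(u) != length(v)) stop("vectors differ in length", call. = FALSE)
  nu <- sqrt(sum(u * u)); nv <- sqrt(sum(v * v))
  if (nu == 0 || nv == 0)
    stop("cosine similarity undefined for a zero-norm vector", call. = FALSE)
  max(-1, min(1, sum(u * v) / (nu * nv)))
}

# Full originals-by-crops cosine matrix from row-wise vector matrices.
cosineMatrix <- function(vecOrig, vecCrop) {
  no <- sqrt(rowSums(vecOrig^2)); nc <- sqrt(rowSums(vecCrop^2))
  if (any(no == 0) || any(nc == 0))
    stop("cosine similarity undefined for a zero-norm vector", call. = FALSE)
  S <- (vecOrig %*% t(vecCrop)) / outer(no, nc)
  S[S > 1] <- 1
  S[S < -1] <- -1
  S
}

#' Greedy lowest-similarity matching over a precomputed similarity matrix
#'
#' Walks the originals in ascending index order; for original `i` the
#' candidate pool is every same-label crop not yet used, excluding crop `i`
#' itself unless it is the only candidate left in the class (crops should
#' come from other patients whenever possible). The candidate with minimal
#' similarity is selected (ties to the lowest crop index) and removed from
#' the pool, so no crop is chosen twice.
#'
#' @param S numeric matrix, `S[i, j]` = similarity of original `i` to crop
#'   `j`; rows and columns index-aligned.
#' @param labels binary labels shared by original `i` and crop `i`.
#' @return a [MatchingPlan-class] with mode `"cross_sequence"`.
#' @export
planFromSimilarity <- function(S, labels) {
  n <- nrow(S)
  labels <- as.integer(labels)
  if (length(labels) != n || ncol(S) != n)
    stop("similarity matrix and labels are not index-aligned", call. = FALSE)
  used <- logical(n)
  cropIdx <- integer(n); simSel <- numeric(n)
  for (i in seq_len(n)) {
    cand <- which(labels == labels[i] & !used)
    nonSelf <- cand[cand != i]
    if (length(nonSelf)) cand <- nonSelf
    if (!length(cand))
      stop("no remaining candidate for original ", i, call. = FALSE)
    j <- cand[which.min(S[i, cand])]   # first minimum = lowest crop index
    cropIdx[i] <- j; simSel[i] <- S[i, j]; used[j] <- TRUE
  }
  new("MatchingPlan",
      pairs = data.frame(original_index = seq_len(n), crop_index = cropIdx,
                         label = labels, similarity = simSel),
      mode = "cross_sequence",
      provenance = list(order = "ascending_index", tieBreak = "lowest_crop_index"))
}

#' Build a cross-sequence matching plan from images
#'
#' Computes raw-pixel similarity vectors for the originals and their ROI
#' crops at a fixed resolution, forms the full cosine matrix, and applies
#' the greedy lowest-similarity, without-replacement rule of
#' [planFromSimilarity()].
#'
#' @param originals list of original-image matrices.
#' @param crops index-aligned list of ROI-crop matrices (crop `i` derives
#'   from original `i`).
#' @param labels binary label per index, shared by original and crop.
#' @param resolution similarity resampling resolution (default 64).
#' @return a [MatchingPlan-class] with mode `"cross_sequence"`.
#' @export
buildCrossSequencePlan <- function(originals, crops, labels, resolution = 64L) {
  if (length(originals) != length(crops) || length(labels) != length(originals))
    stop("originals, crops and labels must be index-aligned", call. = FALSE)
  vo <- t(vapply(originals, flattenForSimilarity, numeric(resolution^2),
                 resolution = resolution))
  vc <- t(vapply(crops, flattenForSimilarity, numeric(resolution^2),
                 resolution = resolution))
  plan <- planFromSimilarity(cosineMatrix(vo, vc), labels)
  plan@provenance$similarityResolution <- as.integer(resolution)
  plan
}

#' Identity pairing for validation and test
#'
#' Pairs every original with its own crop (same index); cross-sequence
#' matching is a training-time device only.
#'
#' @param n number of samples (>= 1).
#' @param labels binary labels of length `n`.
#' @return a [MatchingPlan-class] with mode `"identity"`.
#' @export
identityPlan <- function(n, labels) {
  n <- as.integer(n)
  if (n < 1L) stop("need at least one sample", call. = FALSE)
  if (length(labels) != n) stop("labels must have length n", call. = FALSE)
  new("MatchingPlan",
      pairs = data.frame(original_index = seq_len(n), crop_index = seq_len(n),
                         label = as.integer(labels), similarity = NA_real_),
      mode = "identity", provenance = list())
}

#' @rdname planPairs
#' @export
planMode <- function(plan) plan@mode

#' Accessors for MatchingPlan
#'
#' @param plan a [MatchingPlan-class].
#' @return `planPairs` the pair table; `planMode` the pairing mode.
#' @export
planPairs <- function(plan) plan@pairs

#' Serialize / read a matching plan
#'
#' CSV with columns `original_id,crop_id,label,similarity` plus a JSON
#' provenance sidecar (`<path>.json`).
#'
#' @param plan a [MatchingPlan-class].
#' @param path CSV path.
#' @param sampleIds optional ids to translate indices to.
#' @export
writePlan <- function(plan, path, sampleIds = NULL) {
  p <- plan@pairs
  out <- data.frame(
    original_id = if (is.null(sampleIds)) p$original_index else sampleIds[p$original_index],
    crop_id = if (is.null(sampleIds)) p$crop_index else sampleIds[p$crop_index],
    label = p$label, similarity = p$similarity)
  write.csv(out, path, row.names = FALSE)
  jsonlite::write_json(c(list(mode = plan@mode), plan@provenance),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

setMethod("show", "MatchingPlan", function(object) {
  cat("MatchingPlan (", object@mode, ") with", nrow(object@pairs), "pairs\n")
  if (nrow(object@pairs)) print(head(object@pairs, 5L))
  invisible(NULL)
})
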