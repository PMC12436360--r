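# Gradient-weighted class activation mapping over the original-image branch,
# thresholded to a single bounding box for positive predictions (the
# reader-assistance overlay).

# 4-connected component labels of a logical matrix (breadth-first).
labelComponents4 <- function(mask) {
  lab <- matrix(0L, nrow(mask), ncol(mask))
  nextLab <- 0L
  for (r0 in seq_len(nrow(mask))) for (c0 in seq_len(ncol(mask))) {
    if (!mask[r0, c0] || lab[r0, c0] != 0L) next
    nextLab <- nextLab + 1L
    queue <- list(c(r0, c0))
    lab[r0, c0] <- nextLab
    while (length(queue)) {
      cur <- queue[[1L]]; queue <- queue[-1L]
      for (d in list(c(-1L, 0L), c(1L, 0L), c(0L, -1L), c(0L, 1L))) {
        r <- cur[1] + d[1]; cc <- cur[2] + d[2]
        if (r >= 1L && r <= nrow(mask) && cc >= 1L && cc <= ncol(mask) &&
            mask[r, cc] && lab[r, cc] == 0L) {
          lab[r, cc] <- nextLab
          queue <- c(queue, list(c(r, cc)))
        }
      }
    }
  }
  lab
}

#' Gradient-weighted class activation map for one input
#'
#' Backpropagates the fracture logit to the patch-token activations of the
#' original-image branch and scores each patch token by the total magnitude
#' of its gradient-weighted activation, `sum_d |A[t,d] * G[t,d]|` — the
#' first-order contribution strength of that token to the logit. The
#' activations are taken at the patch-embedding tokens (the first block's
#' input), where token content is still spatially local; at deeper blocks
#' self-attention has mixed the tokens and per-token attribution washes
#' out. The patch-grid map is min-max normalized and bilinearly upsampled
#' to the input resolution. Because of the normalization the map is
#' invariant to rescaling the logit by any positive constant. When every
#' gradient is zero the map is all-zero and flagged `degenerate`
#' (normalization skipped).
#'
#' @param model a [FusionClassifier-class].
#' @param original original-image matrix.
#' @param crop ROI crop (required in multi mode).
#' @param sampleId id recorded on the map.
#' @return a [SaliencyMap-class].
#' @export
saliencyMap <- function(model, original, crop = NULL, sampleId = "") {
  cfgO <- model@encOriginal
  imgO <- resizeBilinear(original, cfgO@imageSize, cfgO@imageSize)
  fo <- encForward(model@params$origEnc, patchify(imgO, cfgO@patchSize), cfgO)
  if (model@mode == "multi") {
    if (is.null(crop)) stop("multi mode requires a crop input", call. = FALSE)
    cfgC <- model@encCrop
    fc <- encForward(model@params$cropEnc,
                     patchify(resizeBilinear(crop, cfgC@imageSize,
                                             cfgC@imageSize),
                              cfgC@patchSize), cfgC)
    feat <- c(fo$feat, fc$feat)
  } else feat <- fo$feat
  hf <- headForward(model@params$head, feat)
  hb <- headBackward(model@params$head, hf, 1)   # d logit / d feature
  Do <- cfgO@embedDim
  bw <- encBackward(model@params$origEnc, fo, hb$dfeat[seq_len(Do)], cfgO)
  acts <- fo$caches[[1L]]$xin[-1L, , drop = FALSE]    # patch-embedding tokens
  grads <- bw$grads$pos[-1L, , drop = FALSE]          # d logit / d token
  raw <- rowSums(abs(acts * grads))
  gp <- cfgO@imageSize %/% cfgO@patchSize
  degenerate <- max(raw) == 0
  if (!degenerate) {
    rng <- range(raw)
    raw <- if (rng[2] > rng[1]) (raw - rng[1]) / (rng[2] - rng[1])
           else rep(1, length(raw))
  }
  grid <- matrix(raw, gp, gp, byrow = TRUE)  # tokens are row-major
  new("SaliencyMap", grid = grid,
      map = resizeBilinear(grid, cfgO@imageSize, cfgO@imageSize),
      sampleId = sampleId, score = sigmoid(hf$logit), degenerate = degenerate)
}

#' Bounding box from a saliency map
#'
#' Returns `NULL` when the model's score falls below the operating point
#' (a negative prediction gets no box) or when no grid cell reaches the
#' activation threshold. Otherwise the tight bounding box — 0-based,
#' half-open, in image pixel coordinates — of the largest 4-connected
#' component of cells at or above the threshold.
#'
#' @param smap a [SaliencyMap-class].
#' @param activationThreshold superlevel threshold in [0,1] on the
#'   normalized map (default 0.5).
#' @param operatingPoint score threshold for calling a fracture.
#' @return integer `(row_min, col_min, row_max, col_max)` or `NULL`.
#' @export
heatmapToBox <- function(smap, activationThreshold = 0.5,
                         operatingPoint = 0.5) {
  stopifnot(is(smap, "SaliencyMap"))
  if (activationThreshold < 0 || activationThreshold > 1)
    stop("activationThreshold must lie in [0,1]", call. = FALSE)
  if (smap@score < operatingPoint) return(NULL)
  mask <- smap@grid >= activationThreshold
  if (smap@degenerate || !any(mask)) return(NULL)
  lab <- labelComponents4(mask)
  sizes <- tabulate(lab[lab > 0L])
  comp <- lab == which.max(sizes)            # ties: first (lowest) label
  rows <- which(apply(comp, 1, any)); cols <- which(apply(comp, 2, any))
  ps <- nrow(smap@map) %/% nrow(smap@grid)
  as.integer(c((min(rows) - 1L) * ps, (min(cols) - 1L) * ps,
               max(rows) * ps, max(cols) * ps))
}

#' Localize fractures over a manifest split
#'
#' Scores every sample and emits a box (via [saliencyMap()] and
#' [heatmapToBox()]) only for predicted positives.
#'
#' @param model a trained [FusionClassifier-class].
#' @param manifest a [DatasetManifest-class].
#' @param split split to process.
#' @param operatingPoint score threshold for a positive call.
#' @param activationThreshold saliency superlevel threshold.
#' @return data.frame `sample_id, score, label, row_min, col_min, row_max,
#'   col_max` with `NA` box coordinates for negative predictions.
#' @export
localizeSamples <- function(model, manifest, split = "test",
                            operatingPoint = 0.5, activationThreshold = 0.5) {
  rec <- manifest@records[manifest@records$split == split, , drop = FALSE]
  if (!nrow(rec)) stop("no samples in split '", split, "'", call. = FALSE)
  out <- NULL
  for (i in seq_len(nrow(rec))) {
    img <- sampleImage(manifest, rec$sample_id[i])
    crop <- cropRoi(img, as.integer(rec[i, c("row_min", "col_min",
                                             "row_max", "col_max")]))
    sm <- saliencyMap(model, img, crop, sampleId = rec$sample_id[i])
    box <- heatmapToBox(sm, activationThreshold, operatingPoint)
    out <- rbind(out, data.frame(
      sample_id = rec$sample_id[i], score = sm@score, label = rec$label[i],
      row_min = if (is.null(box)) NA_integer_ else box[1],
      col_min = if (is.null(box)) NA_integer_ else box[2],
      row_max = if (is.null(box)) NA_integer_ else box[3],
      col_max = if (is.null(box)) NA_integer_ else box[4]))
  }
  out
}

#' Write an overlay PNG with the detection box drawn on the image
#'
#' @param image grayscale matrix in [0,1].
#' @param box 0-based half-open box in the coordinates of `image` (or
#'   `NULL` for no box).
#' @param path output PNG path.
#' @param intensity border intensity.
#' @return the path, invisibly.
#' @export
renderOverlay <- function(image, box, path, intensity = 1) {
  if (!is.null(box)) {
    rows <- boxRows(box); cols <- boxCols(box)
    image[range(rows), cols] <- intensity
    image[rows, range(cols)] <- intensity
  }
  png::writePNG(clamp01(image), path)
  invisible(path)
}

setMethod("show", "SaliencyMap", function(object) {
  cat("SaliencyMap", object@sampleId, ":", nrow(object@grid), "x",
      ncol(object@grid), "grid | score", sprintf("%.3f", object@score),
      if (object@degenerate) "| degenerate (all-zero)", "\n")
  invisible(NULL)
})
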