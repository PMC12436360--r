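# Synthetic orbital-radiograph phantoms.
#
# Each phantom is a deterministic function of (seed, label, site, config):
# a vertical background gradient, an elliptical head outline, two bright
# annular orbital rims, and for positives a localized rim discontinuity
# (intensity drop of amplitude fractureContrast) at the named site. The
# additive noise layer is drawn from the per-sample seed *independently of
# the label*, so a positive and negative render of the same seed differ
# only inside the declared fracture region.

#' Construct a phantom-generator configuration
#'
#' Defaults mirror the clinical population the phantoms emulate: 18%
#' fracture prevalence, and a fracture-site distribution with the orbital
#' floor most common (35%), then multiple sites (32%) and the medial wall
#' (28%), with superior (5%) and lateral (1%) fractures rare. Site
#' probabilities default to the exact cohort fractions (116, 91, 16, 3,
#' 104)/330 so they sum to one exactly.
#'
#' @param nSamples number of phantoms.
#' @param prevalence fracture prevalence in (0,1).
#' @param siteProbs probability vector over
#'   (floor, medial, superior, lateral, multiple).
#' @param imageSize square image side in pixels.
#' @param fractureContrast intensity drop of the rim discontinuity.
#' @param noiseSd additive Gaussian noise standard deviation.
#' @param exactCounts force exactly `round(nSamples * prevalence)` positives.
#' @param roiTightness `"head"` or `"orbit"` ROI boxes.
#' @param seed master seed.
#' @return A [PhantomConfig-class] object.
#' @export
phantomConfig <- function(nSamples = 100L, prevalence = 0.18,
                          siteProbs = c(floor = 116, medial = 91,
                                        superior = 16, lateral = 3,
                                        multiple = 104) / 330,
                          imageSize = 128L, fractureContrast = 0.4,
                          noiseSd = 0.03, exactCounts = FALSE,
                          roiTightness = "head", seed = 1L) {
  new("PhantomConfig", nSamples = as.integer(nSamples),
      prevalence = prevalence, siteProbs = siteProbs,
      imageSize = as.integer(imageSize), fractureContrast = fractureContrast,
      noiseSd = noiseSd, exactCounts = exactCounts,
      roiTightness = roiTightness, seed = as.integer(seed))
}

# Normalized pixel-center coordinate fields (x across columns, y down rows)
# and the geometric primitives shared by the renderer and the masks.
phantomGeometry <- function(config) {
  n <- config@imageSize
  y <- matrix((seq_len(n) - 0.5) / n, n, n)         # varies along rows
  x <- matrix((seq_len(n) - 0.5) / n, n, n, byrow = TRUE)
  headE <- ((y - 0.50) / 0.45)^2 + ((x - 0.50) / 0.38)^2
  orbY <- 0.42; orbXL <- 0.33; orbXR <- 1 - orbXL
  r0 <- 0.13; halfT <- 0.022
  dL <- sqrt((y - orbY)^2 + (x - orbXL)^2)
  dR <- sqrt((y - orbY)^2 + (x - orbXR)^2)
  list(n = n, x = x, y = y, headE = headE, orbY = orbY, orbXL = orbXL,
       orbXR = orbXR, r0 = r0, halfT = halfT, dL = dL, dR = dR,
       rimL = abs(dL - r0) <= halfT, rimR = abs(dR - r0) <= halfT)
}

# Angular window over a radial band of one orbit. The default band is the
# rim itself; the displaced-fragment band sits just inside it.
siteWindow <- function(geo, side, centerAngle, halfWidth = 0.5,
                       band = c("rim", "fragment")) {
  band <- match.arg(band)
  x0 <- if (side == "L") geo$orbXL else geo$orbXR
  d0 <- if (side == "L") geo$dL else geo$dR
  radial <- if (band == "rim") abs(d0 - geo$r0) <= geo$halfT
            else d0 >= geo$r0 - 3.5 * geo$halfT & d0 <= geo$r0 - 1.5 * geo$halfT
  ang <- atan2(geo$y - geo$orbY, geo$x - x0)
  dAng <- abs(atan2(sin(ang - centerAngle), cos(ang - centerAngle)))
  radial & dAng <= halfWidth
}

# Gap (rim break) and displaced-fragment components of a fracture site.
siteComponents <- function(site, geo) {
  w <- function(side, ang) list(
    gap = siteWindow(geo, side, ang, band = "rim"),
    fragment = siteWindow(geo, side, ang, band = "fragment"))
  switch(site,
    floor    = list(w("R", pi / 2)),
    superior = list(w("R", -pi / 2)),
    medial   = list(w("R", pi)),     # toward midline for the right orbit
    lateral  = list(w("R", 0)),
    multiple = list(w("R", pi / 2), w("L", 0)))
}

#' Pixel mask of the fracture region for a site
#'
#' Union of the rim gap and the displaced-fragment band of the site.
#' Deterministic in the configuration alone (the phantom geometry carries no
#' randomness; only the noise layer is seeded), so the mask delimits exactly
#' the pixels in which a positive and a negative render of the same seed may
#' differ. Single sites are drawn on the right orbit: `floor` at the bottom
#' of the rim, `superior` at the top, `medial` toward the midline, `lateral`
#' on the temporal side; `multiple` combines a right-orbit floor fracture
#' with a left-orbit lateral one.
#'
#' @param site fracture site (not `"none"`).
#' @param config a [PhantomConfig-class].
#' @return logical matrix.
#' @export
fractureMask <- function(site, config) {
  stopifnot(is(config, "PhantomConfig"))
  if (!site %in% SITE_LEVELS[-1])
    stop("no fracture mask for site '", site, "'", call. = FALSE)
  geo <- phantomGeometry(config)
  comps <- siteComponents(site, geo)
  Reduce(`|`, lapply(comps, function(cc) cc$gap | cc$fragment))
}

# Bounding box (0-based half-open) of a logical mask, with margin, clipped.
maskBox <- function(mask, margin = 2L) {
  rows <- which(apply(mask, 1, any)); cols <- which(apply(mask, 2, any))
  c(max(0L, min(rows) - 1L - margin), max(0L, min(cols) - 1L - margin),
    min(nrow(mask), max(rows) + margin), min(ncol(mask), max(cols) + margin))
}

# Noise-free phantom plus ROI box; exactly mirror-symmetric about the
# vertical midline when label = 0.
phantomBase <- function(label, site, config) {
  geo <- phantomGeometry(config)
  img <- 0.10 + 0.10 * geo$y                       # background gradient
  img[geo$headE <= 1] <- 0.30                      # head
  img[geo$headE <= 1 & geo$headE >= 0.90] <- 0.55  # skull outline
  img[geo$dL < geo$r0 - geo$halfT] <- 0.20         # orbit interiors
  img[geo$dR < geo$r0 - geo$halfT] <- 0.20
  img[geo$rimL | geo$rimR] <- 0.85                 # bright orbital rims
  if (label == 1L) {
    # rim break (intensity drop) plus a displaced bright fragment just
    # inside the rim: the step discontinuity of a displaced fracture
    for (cc in siteComponents(site, geo)) {
      img[cc$gap] <- 0.85 - config@fractureContrast
      img[cc$fragment] <- 0.15 + config@fractureContrast
    }
  }
  roi <- if (config@roiTightness == "orbit") {
    maskBox(geo$dL <= geo$r0 + geo$halfT | geo$dR <= geo$r0 + geo$halfT)
  } else {
    maskBox(geo$headE <= 1)
  }
  list(img = img, roi = roi)
}

#' Render one phantom radiograph
#'
#' Deterministic function of `(seed, label, site, config)`. The noise layer
#' is drawn from `seed` before the label is consulted, so renders of the two
#' labels under the same seed share the identical noise realization.
#'
#' @param seed integer seed for the noise layer.
#' @param label 0 (normal) or 1 (fracture).
#' @param site fracture site; must be `"none"` iff `label == 0`.
#' @param config a [PhantomConfig-class].
#' @param sampleId id to stamp on the sample.
#' @return A [RadiographSample-class].
#' @export
renderPhantom <- function(seed, label, site = if (label == 0L) "none" else "floor",
                          config = phantomConfig(),
                          sampleId = sprintf("phantom_seed%d", as.integer(seed))) {
  label <- as.integer(label)
  if ((site == "none") != (label == 0L))
    stop("site must be 'none' if and only if label is 0", call. = FALSE)
  base <- phantomBase(label, site, config)
  noise <- withSeed(seed, matrix(rnorm(config@imageSize^2, 0, config@noiseSd),
                                 config@imageSize, config@imageSize))
  new("RadiographSample", sampleId = sampleId,
      pixels = clamp01(base$img + noise), label = label,
      roi = as.integer(base$roi), site = site, seed = as.integer(seed))
}

#' Generate a reproducible phantom dataset
#'
#' Labels are Bernoulli(`prevalence`) draws (or an exact count when
#' `exactCounts`), fracture sites of positives are drawn from `siteProbs`,
#' and every per-sample render seed derives from `config@seed`, so the same
#' configuration always yields the identical dataset.
#'
#' @param config a [PhantomConfig-class]; `nSamples >= 2` required.
#' @return A [DatasetManifest-class] holding the rendered images in memory,
#'   all split tags `"unassigned"`.
#' @export
generatePhantomDataset <- function(config = phantomConfig()) {
  n <- config@nSamples
  if (n < 2L) stop("need at least 2 samples", call. = FALSE)
  draws <- withSeed(config@seed, {
    labels <- if (config@exactCounts) {
      k <- as.integer(round(n * config@prevalence))
      sample(c(rep(1L, k), rep(0L, n - k)))
    } else as.integer(rbinom(n, 1L, config@prevalence))
    sites <- rep("none", n)
    npos <- sum(labels)
    if (npos > 0L)
      sites[labels == 1L] <- sample(names(config@siteProbs), npos,
                                    replace = TRUE, prob = config@siteProbs)
    list(labels = labels, sites = sites,
         seeds = sample.int(.Machine$integer.max - 1L, n))
  })
  ids <- sprintf("phantom_%04d", seq_len(n))
  images <- vector("list", n); names(images) <- ids
  rois <- matrix(0L, n, 4L)
  for (i in seq_len(n)) {
    s <- renderPhantom(draws$seeds[i], draws$labels[i], draws$sites[i],
                       config, sampleId = ids[i])
    images[[i]] <- s@pixels
    rois[i, ] <- s@roi
  }
  records <- data.frame(
    sample_id = ids, path = NA_character_, label = draws$labels,
    row_min = rois[, 1], col_min = rois[, 2], row_max = rois[, 3],
    col_max = rois[, 4], site = draws$sites, split = "unassigned",
    stringsAsFactors = FALSE)
  new("DatasetManifest", records = records, images = images,
      provenance = list(config = configAsList(config),
                        sampleSeeds = draws$seeds))
}

configAsList <- function(config) {
  list(nSamples = config@nSamples, prevalence = config@prevalence,
       siteProbs = as.list(config@siteProbs), imageSize = config@imageSize,
       fractureContrast = config@fractureContrast, noiseSd = config@noiseSd,
       exactCounts = config@exactCounts, roiTightness = config@roiTightness,
       seed = config@seed)
}

#' Crop the region of interest out of a sample
#'
#' Returns the ROI sub-grid of the pixels; by construction the crop keeps
#' the label of its source image (cropping removes only diagnostically
#' irrelevant background).
#'
#' @param x a [RadiographSample-class], or a numeric matrix.
#' @param roi 0-based half-open box, required when `x` is a matrix.
#' @return numeric matrix of shape `(row_max - row_min, col_max - col_min)`.
#' @export
setGeneric("cropRoi", function(x, roi) standardGeneric("cropRoi"))

#' @rdname cropRoi
#' @export
setMethod("cropRoi", "RadiographSample", function(x, roi) {
  cropRoi(x@pixels, x@roi)
})

#' @rdname cropRoi
#' @export
setMethod("cropRoi", "matrix", function(x, roi) {
  roi <- as.integer(roi)
  if (length(roi) != 4L || roi[1] < 0L || roi[2] < 0L ||
      roi[1] >= roi[3] || roi[2] >= roi[4] ||
      roi[3] > nrow(x) || roi[4] > ncol(x))
    stop("roi outside image bounds", call. = FALSE)
  x[boxRows(roi), boxCols(roi), drop = FALSE]
})

# Largest-remainder apportionment of `total` into parts proportional to
# `ratios`; remainder ties resolved in part order.
largestRemainder <- function(total, ratios) {
  quota <- total * ratios / sum(ratios)
  base <- floor(quota)
  left <- total - sum(base)
  if (left > 0) {
    ord <- order(-(quota - base), seq_along(ratios))
    base[ord[seq_len(left)]] <- base[ord[seq_len(left)]] + 1
  }
  as.integer(base)
}

#' Assign train/tune/test split tags, stratified by label
#'
#' Splits at the sample level within each label class, with per-class part
#' sizes fixed by largest-remainder rounding of the ratios and the class
#' order shuffled deterministically from `seed`.
#'
#' @param manifest a [DatasetManifest-class].
#' @param ratios non-negative triple (train, tune, test), sum > 0.
#' @param seed integer seed controlling the shuffle.
#' @return the manifest with `split` tags filled in. A warning is raised for
#'   any class with fewer members than non-empty split parts.
#' @export
splitDataset <- function(manifest, ratios = c(7, 1, 2), seed = 1L) {
  stopifnot(is(manifest, "DatasetManifest"), length(ratios) == 3L)
  if (any(ratios < 0) || sum(ratios) <= 0)
    stop("ratios must be non-negative with positive sum", call. = FALSE)
  rec <- manifest@records
  split <- rep(NA_character_, nrow(rec))
  parts <- c("train", "tune", "test")
  for (lab in sort(unique(rec$label))) {
    idx <- which(rec$label == lab)
    if (length(idx) < sum(ratios > 0))
      warning("label class ", lab, " has fewer samples (", length(idx),
              ") than non-empty split parts", call. = FALSE)
    sizes <- largestRemainder(length(idx), ratios)
    ord <- withSeed(seed + lab, sample(idx))
    split[ord] <- rep(parts, sizes)
  }
  manifest@records$split <- split
  manifest@provenance$splitRatios <- ratios
  manifest@provenance$splitSeed <- as.integer(seed)
  validObject(manifest)
  manifest
}

#' Randomly subsample negatives in the train and tune splits
#'
#' Balances the development splits by retaining at most
#' `floor(n_pos * negPosRatio)` randomly chosen negatives per split; the
#' test split is never touched, so evaluation keeps the natural prevalence.
#'
#' @param manifest a split-tagged [DatasetManifest-class].
#' @param negPosRatio maximum negatives-per-positive ratio (> 0); default 1.
#' @param seed integer seed.
#' @return the reduced manifest.
#' @export
subsampleNegatives <- function(manifest, negPosRatio = 1, seed = 1L) {
  stopifnot(is(manifest, "DatasetManifest"))
  if (negPosRatio <= 0) stop("negPosRatio must be > 0", call. = FALSE)
  rec <- manifest@records
  if (all(rec$split == "unassigned"))
    stop("manifest carries no split tags; call splitDataset() first",
         call. = FALSE)
  drop <- integer()
  for (sp in c("train", "tune")) {
    pos <- which(rec$split == sp & rec$label == 1L)
    neg <- which(rec$split == sp & rec$label == 0L)
    if (!length(pos) && length(neg)) {
      warning("split '", sp, "' has no positives; negatives left untouched",
              call. = FALSE)
      next
    }
    keep <- min(length(neg), floor(length(pos) * negPosRatio))
    if (length(neg) > keep) {
      kept <- withSeed(seed + match(sp, SPLIT_LEVELS),
                       sort(sample(neg, keep)))
      drop <- c(drop, setdiff(neg, kept))
    }
  }
  if (length(drop)) {
    gone <- rec$sample_id[drop]
    manifest@records <- rec[-drop, , drop = FALSE]
    rownames(manifest@records) <- NULL
    manifest@images <- manifest@images[setdiff(names(manifest@images), gone)]
  }
  manifest@provenance$negPosRatio <- negPosRatio
  manifest
}

#' @describeIn splitCounts-helpers Per-split label counts (internal helper).
#' @noRd
splitCounts <- function(manifest) {
  table(split = manifest@records$split, label = manifest@records$label)
}

#' Accessors for DatasetManifest
#'
#' `manifestRecords` returns the sample table; `sampleImage` one pixel grid;
#' `manifestImages` the named list of grids (loading from disk paths when the
#' images are not held in memory).
#'
#' @param manifest a [DatasetManifest-class].
#' @param sampleId a sample id.
#' @return data.frame, matrix, or list of matrices respectively.
#' @export
manifestRecords <- function(manifest) manifest@records

#' @rdname manifestRecords
#' @export
sampleImage <- function(manifest, sampleId) {
  img <- manifest@images[[sampleId]]
  if (is.null(img)) {
    path <- manifest@records$path[manifest@records$sample_id == sampleId]
    if (length(path) != 1L || is.na(path))
      stop("no image stored or on disk for ", sampleId, call. = FALSE)
    img <- readGrayPng(path)
  }
  img
}

#' @rdname manifestRecords
#' @export
manifestImages <- function(manifest) {
  out <- lapply(manifest@records$sample_id, function(id) sampleImage(manifest, id))
  names(out) <- manifest@records$sample_id
  out
}

setMethod("show", "DatasetManifest", function(object) {
  rec <- object@records
  cat("DatasetManifest with", nrow(rec), "samples (",
      sum(rec$label == 1L), "fracture /", sum(rec$label == 0L), "normal )\n")
  if (!all(rec$split == "unassigned")) print(splitCounts(object))
  invisible(NULL)
})

setMethod("show", "RadiographSample", function(object) {
  cat("RadiographSample", object@sampleId, ":", nrow(object@pixels), "x",
      ncol(object@pixels), "| label", object@label, "| site", object@site,
      "| roi [", paste(object@roi, collapse = ", "), ")\n")
  invisible(NULL)
})
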