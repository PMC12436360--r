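# Shared numeric helpers: bilinear resampling, seeded RNG, box arithmetic.

#' Resample an intensity grid to a target size by bilinear interpolation
#'
#' Thin wrapper around [EBImage::resize()]. When the image already has the
#' target shape it is returned unchanged, so the identity case is exact.
#'
#' @param image numeric matrix.
#' @param rows,cols target shape.
#' @return numeric matrix of dimension `rows x cols`.
#' @export
resizeBilinear <- function(image, rows, cols = rows) {
  stopifnot(is.matrix(image), rows >= 1, cols >= 1)
  if (nrow(image) == rows && ncol(image) == cols) return(image)
  out <- EBImage::imageData(EBImage::resize(image, w = rows, h = cols,
                                            filter = "bilinear"))
  dim(out) <- c(rows, cols)
  out
}

# Evaluate `code` under a temporary RNG state seeded with `seed`.
withSeed <- function(seed, code) {
  withr::with_seed(as.integer(seed), code)
}

# Deterministic child seeds below 2^31, derived from a master seed.
deriveSeeds <- function(seed, n) {
  withSeed(seed, sample.int(.Machine$integer.max - 1L, n))
}

# 0-based half-open box -> 1-based inclusive row/col index vectors.
boxRows <- function(box) (box[1] + 1L):box[3]
boxCols <- function(box) (box[2] + 1L):box[4]

clamp01 <- function(x) {   # keeps dim attributes, unlike pmin/pmax(0, x)
  x[x < 0] <- 0
  x[x > 1] <- 1
  x
}

sigmoid <- function(x) 1 / (1 + exp(-x))

stopIfNot01Matrix <- function(image, what = "image") {
  if (!is.matrix(image) || length(image) == 0L)
    stop(what, " must be a non-empty numeric matrix", call. = FALSE)
  if (any(!is.finite(image)))
    stop(what, " contains non-finite intensities", call. = FALSE)
  invisible(TRUE)
}
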