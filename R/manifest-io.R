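# Dataset materialization: 8-bit grayscale PNGs plus a manifest CSV with
# header sample_id,path,label,row_min,col_min,row_max,col_max,site,split
# and a JSON provenance sidecar.

readGrayPng <- function(path) {
  px <- png::readPNG(path)
  if (length(dim(px)) == 3L) px <- px[, , 1L]    # first channel of RGB(A)
  rng <- range(px)
  if (rng[2] > rng[1]) px <- (px - rng[1]) / (rng[2] - rng[1])
  px
}

#' Write a dataset to disk
#'
#' Materializes every image as an 8-bit grayscale PNG under `dir/images/`,
#' writes `manifest.csv` and a `provenance.json` carrying the generating
#' configuration.
#'
#' @param manifest a [DatasetManifest-class] with in-memory images.
#' @param dir output directory (created if needed).
#' @return the manifest with `path` columns filled in, invisibly.
#' @export
writeDataset <- function(manifest, dir) {
  stopifnot(is(manifest, "DatasetManifest"))
  imgDir <- file.path(dir, "images")
  dir.create(imgDir, recursive = TRUE, showWarnings = FALSE)
  rec <- manifest@records
  for (i in seq_len(nrow(rec))) {
    id <- rec$sample_id[i]
    path <- file.path(imgDir, paste0(id, ".png"))
    png::writePNG(sampleImage(manifest, id), path)
    rec$path[i] <- file.path("images", paste0(id, ".png"))
  }
  manifest@records <- rec
  write.csv(rec, file.path(dir, "manifest.csv"), row.names = FALSE)
  jsonlite::write_json(manifest@provenance, file.path(dir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}

#' Read a dataset from disk
#'
#' Loads `manifest.csv` plus the referenced PNGs; each image is min-max
#' normalized to [0,1] on load.
#'
#' @param dir directory written by [writeDataset()].
#' @return a [DatasetManifest-class] with images in memory.
#' @export
readDataset <- function(dir) {
  rec <- read.csv(file.path(dir, "manifest.csv"), stringsAsFactors = FALSE)
  rec$label <- as.integer(rec$label)
  for (cl in c("row_min", "col_min", "row_max", "col_max"))
    rec[[cl]] <- as.integer(rec[[cl]])
  images <- lapply(rec$path, function(p) readGrayPng(file.path(dir, p)))
  names(images) <- rec$sample_id
  prov <- list()
  pj <- file.path(dir, "provenance.json")
  if (file.exists(pj)) prov <- jsonlite::read_json(pj, simplifyVector = TRUE)
  new("DatasetManifest", records = rec, images = images, provenance = prov)
}
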