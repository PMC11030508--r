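# Raster I/O: 32-bit float TIFF for phase/RI images, integer TIFF for
# label masks, multi-frame TIFF for raw acquisitions.

#' Write and read floating-point images as TIFF
#'
#' Phase maps, refractive-index maps and density maps are stored as 32-bit
#' float TIFF; label masks as 8-bit integer TIFF.
#'
#' @param img numeric matrix (or `[rows, cols, frames]` array).
#' @param path output path.
#' @return `write_image_tiff` returns `path` invisibly; `read_image_tiff`
#'   returns a matrix or array.
#' @export
write_image_tiff <- function(img, path) {
  if (inherits(img, "phase_map")) img <- img$phase
  if (inherits(img, "ri_map")) img <- img$n_abs
  if (length(dim(img)) == 3) {
    frames <- lapply(seq_len(dim(img)[3]), function(i) img[, , i])
    tiff::writeTIFF(frames, path, bits.per.sample = 32, reduce = FALSE)
  } else {
    tiff::writeTIFF(img, path, bits.per.sample = 32, reduce = FALSE)
  }
  invisible(path)
}

#' @rdname write_image_tiff
#' @export
read_image_tiff <- function(path) {
  x <- tiff::readTIFF(path, all = TRUE)
  if (length(x) == 1) return(x[[1]])
  simplify2array(x)
}

#' Write an integer label mask as TIFF
#' @param labels integer matrix of compartment codes (0-255).
#' @param path output path.
#' @export
write_labels_tiff <- function(labels, path) {
  tiff::writeTIFF(labels / 255, path, bits.per.sample = 8)
  invisible(path)
}

#' @rdname write_labels_tiff
#' @export
read_labels_tiff <- function(path) {
  m <- tiff::readTIFF(path)
  matrix(as.integer(round(m * 255)), nrow(m), ncol(m))
}
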