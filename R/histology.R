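# Oil-Red-O histology quantification: optical-density conversion,
# FastRed/FastBlue color deconvolution, thresholding and particle counts.

#' Stain matrix for color deconvolution
#'
#' Columns are unit optical-density vectors for the two stains plus an
#' orthogonal residual vector.  The FastRed/FastBlue preset uses the
#' standard published color-deconvolution vectors for those dyes.
#'
#' @param preset `"fastred_fastblue"` or `"custom"`.
#' @param stains for `"custom"`, a 3 x 2 matrix of OD vectors (columns).
#' @return 3 x 3 matrix of class `stain_matrix` with columns `red`,
#'   `blue`, `residual`.
#' @export
stain_matrix <- function(preset = c("fastred_fastblue", "custom"),
                         stains = NULL) {
  preset <- match.arg(preset)
  if (preset == "fastred_fastblue") {
    v1 <- c(0.21393921, 0.85112669, 0.47794022)   # FastRed
    v2 <- c(0.74890292, 0.60624161, 0.26731082)   # FastBlue
  } else {
    if (is.null(stains) || !all(dim(stains) == c(3, 2)))
      stopf("custom preset needs a 3 x 2 stain matrix")
    v1 <- stains[, 1]; v2 <- stains[, 2]
  }
  v1 <- v1 / sqrt(sum(v1^2))
  v2 <- v2 / sqrt(sum(v2^2))
  v3 <- c(v1[2] * v2[3] - v1[3] * v2[2],
          v1[3] * v2[1] - v1[1] * v2[3],
          v1[1] * v2[2] - v1[2] * v2[1])
  if (sqrt(sum(v3^2)) < 1e-8) stopf("stain vectors are collinear")
  v3 <- v3 / sqrt(sum(v3^2))
  M <- cbind(red = v1, blue = v2, residual = v3)
  rownames(M) <- c("R", "G", "B")
  class(M) <- c("stain_matrix", class(M))
  M
}

#' Convert an RGB image to optical density
#'
#' Beer-Lambert: OD = -log10(I / I0) per channel.  Zero (or negative)
#' intensities are clipped to one count (I0/255) and counted in the
#' `clipped` attribute.
#'
#' @param img numeric array `[rows, cols, 3]` with intensities in (0, I0].
#' @param I0 white level (default 1).
#' @return array of optical densities with attribute `clipped`.
#' @export
rgb_to_od <- function(img, I0 = 1) {
  stopifnot(length(dim(img)) == 3, dim(img)[3] == 3)
  floor_val <- I0 / 255
  nclip <- sum(img < floor_val)
  if (nclip > 0) {
    warnf("%d intensities below one count clipped", nclip)
    img[img < floor_val] <- floor_val
  }
  od <- -log10(img / I0)
  attr(od, "clipped") <- nclip
  od
}

#' Inverse of [rgb_to_od()]
#' @param od optical-density array.
#' @param I0 white level.
#' @return RGB intensity array.
#' @export
od_to_rgb <- function(od, I0 = 1) I0 * 10^(-od)

#' Separate stains by color deconvolution
#'
#' Applies the inverse stain matrix pixel-wise to the optical-density
#' image, returning per-stain density maps.  The residual channel is kept
#' for quality control.
#'
#' @param od optical-density array `[rows, cols, 3]`.
#' @param M a [stain_matrix()].
#' @return list of matrices `red`, `blue`, `residual`.
#' @export
color_deconvolve <- function(od, M = stain_matrix()) {
  stopifnot(length(dim(od)) == 3, dim(od)[3] == 3)
  Minv <- tryCatch(solve(unclass(M)), error = function(e)
    stopf("stain matrix is singular"))
  nr <- dim(od)[1]; nc <- dim(od)[2]
  flat <- matrix(od, nr * nc, 3)
  dens <- flat %*% t(Minv)
  list(red = matrix(dens[, 1], nr, nc),
       blue = matrix(dens[, 2], nr, nc),
       residual = matrix(dens[, 3], nr, nc))
}

#' Synthesize an ORO/Hematoxylin histology image from a phantom
#'
#' Lipid droplets take the FastRed (ORO) stain density and nucleus-dense
#' compartments (rosette cells, directional cells) the FastBlue
#' (Hematoxylin counterstain) density; RGB = I0 * 10^(-M d).  A phantom
#' with no droplets and no nucleus-dense labels gives a pure-white image.
#'
#' @param truth an `organoid_phantom`.
#' @param M a [stain_matrix()].
#' @param d_red,d_blue stain densities on droplet / nuclear labels (>= 0).
#' @param d_tissue faint blue density over the rest of the organoid.
#' @param I0 white level.
#' @return list with `rgb` (array), `density_red`, `density_blue`.
#' @export
simulate_oro_histology <- function(truth, M = stain_matrix(),
                                   d_red = 1.0, d_blue = 0.7,
                                   d_tissue = 0.05, I0 = 1) {
  stopifnot(inherits(truth, "organoid_phantom"))
  if (d_red < 0 || d_blue < 0 || d_tissue < 0)
    stopf("stain densities must be non-negative")
  lab <- truth$labels
  dr <- matrix(0, nrow(lab), ncol(lab))
  db <- matrix(0, nrow(lab), ncol(lab))
  dr[lab == LABELS["droplet"]] <- d_red
  db[lab %in% LABELS[c("rosette", "directional_cell")]] <- d_blue
  db[lab %in% LABELS[c("cytoplasm", "lumen", "fissure")]] <- d_tissue
  od <- array(0, c(nrow(lab), ncol(lab), 3))
  for (ch in 1:3) od[, , ch] <- M[ch, 1] * dr + M[ch, 2] * db
  list(rgb = od_to_rgb(od, I0), density_red = dr, density_blue = db)
}

#' Threshold a stain density map and count particles
#'
#' Connected components (8-connectivity by default) of the supra-threshold
#' red-stain density within the tissue mask; components smaller than
#' `min_particle_px` are removed.  Both the particle (component) count and
#' the positive-pixel count are reported, the latter normalized by the
#' tissue area.
#'
#' @param red_density matrix of ORO stain density.
#' @param tissue_mask binary matrix of the tissue region.
#' @param threshold density threshold; default is Otsu's threshold of the
#'   density values within the tissue.
#' @param min_particle_px minimum component size, pixels.
#' @param connectivity 4 or 8.
#' @param closing_px optional morphological closing (disc diameter in px)
#'   applied to the thresholded mask before counting; 0 disables.
#' @return object of class `particle_stats`: `particle_count`,
#'   `positive_pixels`, `tissue_pixels`, `normalized_density`, `threshold`,
#'   `mask`.
#' @export
threshold_and_count <- function(red_density, tissue_mask, threshold = NULL,
                                min_particle_px = 4, connectivity = 8,
                                closing_px = 0) {
  tissue_mask <- tissue_mask > 0
  if (!any(tissue_mask)) stopf("tissue mask is empty")
  if (!all(dim(red_density) == dim(tissue_mask)))
    stopf("density map and tissue mask shapes differ")
  if (is.null(threshold)) {
    threshold <- otsu_threshold(red_density[tissue_mask])
    if (is.na(threshold)) threshold <- Inf   # featureless density map
  }
  mask <- (red_density >= threshold) & tissue_mask
  if (closing_px > 0 && any(mask))
    mask <- EBImage::closing(mask + 0,
                             EBImage::makeBrush(2L * ceiling(closing_px / 2) + 1L,
                                                "box")) > 0 & tissue_mask
  lab <- label_components(mask, connectivity)
  n <- max(lab)
  if (n > 0) {
    sizes <- tabulate(lab[lab > 0], n)
    small <- which(sizes < min_particle_px)
    if (length(small)) {
      mask[lab %in% small] <- FALSE
      n <- n - length(small)
    }
  }
  structure(list(particle_count = n, positive_pixels = sum(mask),
                 tissue_pixels = sum(tissue_mask),
                 normalized_density = sum(mask) / sum(tissue_mask),
                 threshold = threshold, mask = mask),
            class = "particle_stats")
}

#' @export
print.particle_stats <- function(x, ...) {
  cat(sprintf("ORO particles: %d (positive px %d / tissue px %d = %.4f; threshold %.4g)\n",
              x$particle_count, x$positive_pixels, x$tissue_pixels,
              x$normalized_density, x$threshold))
  invisible(x)
}
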