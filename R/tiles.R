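# Tile-wise feature extraction: texture (GLCM), fractal/granulometry,
# Fourier-spectrum and autocorrelation families on 50 um tiles.

#' Configuration of the tile feature extractor
#'
#' @param tile_size_um tile side, micrometres (default 50).
#' @param stride_um tile stride; defaults to `tile_size_um` (no overlap).
#' @param families feature families to compute.
#' @param glcm_levels gray levels for co-occurrence quantization.
#' @param glcm_offsets list of `(drow, dcol)` offsets; the default covers
#'   0, 45, 90 and 135 degrees at 1 px.
#' @param fractal_bands list of micrometre scale bands for band-limited
#'   box-counting dimensions.
#' @param curve_band_um curvature-diameter band for the curvilinear
#'   pattern score.
#' @param circle_band_um2 disk-area band for the circular pattern score.
#' @param binarize binarization rule for the fractal family: `"mad"`
#'   (foreground above median + `mad_k` * MAD; robust on mostly-background
#'   tiles) or `"otsu"` (for genuinely bimodal inputs).
#' @param mad_k MAD multiplier for the `"mad"` rule.
#' @return object of class `tile_config`.
#' @export
tile_config <- function(tile_size_um = 50, stride_um = tile_size_um,
                        families = c("glcm", "fractal", "fourier", "autocorr"),
                        glcm_levels = 32,
                        glcm_offsets = list(c(0, 1), c(-1, 1), c(-1, 0), c(-1, -1)),
                        fractal_bands = list(band_5_9um = c(5, 9),
                                             band_17_23um = c(17, 23)),
                        curve_band_um = c(4, 8),
                        circle_band_um2 = c(34, 38),
                        binarize = c("mad", "otsu"),
                        mad_k = 2) {
  binarize <- match.arg(binarize)
  structure(list(tile_size_um = tile_size_um, stride_um = stride_um,
                 families = families, glcm_levels = as.integer(glcm_levels),
                 glcm_offsets = glcm_offsets, fractal_bands = fractal_bands,
                 curve_band_um = curve_band_um, circle_band_um2 = circle_band_um2,
                 binarize = binarize, mad_k = mad_k),
            class = "tile_config")
}

#' Subdivide an image into square tiles
#'
#' Row-major grid of full tiles; partial edge tiles are discarded.
#'
#' @param image numeric matrix.
#' @param pixel_size micrometres per pixel.
#' @param tile_size_um tile side, micrometres.
#' @param stride_um stride between tile origins.
#' @return list with `tiles` (list of matrices), `grid` (data.frame of tile
#'   row/col indices and pixel origins) and `tile_px`.
#' @export
tile_image <- function(image, pixel_size, tile_size_um = 50,
                       stride_um = tile_size_um) {
  tpx <- round(tile_size_um / pixel_size)
  spx <- round(stride_um / pixel_size)
  if (tpx < 10) stopf("tile size %.3g um is below 10 px at %.3g um/px",
                      tile_size_um, pixel_size)
  nr <- nrow(image); nc <- ncol(image)
  r0 <- seq(1L, nr - tpx + 1L, by = spx)
  c0 <- seq(1L, nc - tpx + 1L, by = spx)
  tiles <- list(); grid <- NULL; k <- 0L
  for (i in seq_along(r0)) for (j in seq_along(c0)) {
    k <- k + 1L
    tiles[[k]] <- image[r0[i]:(r0[i] + tpx - 1L), c0[j]:(c0[j] + tpx - 1L)]
    grid <- rbind(grid, data.frame(tile = k, row = i, col = j,
                                   r0 = r0[i], c0 = c0[j]))
  }
  list(tiles = tiles, grid = grid, tile_px = tpx)
}

# --- texture (Haralick / GLCM) ------------------------------------------

quantize_tile <- function(tile, levels, probs = c(0.01, 0.99)) {
  q <- stats::quantile(tile, probs, names = FALSE)
  if (diff(q) <= 0) return(matrix(1L, nrow(tile), ncol(tile)))
  x <- pmin(pmax(tile, q[1]), q[2])
  matrix(pmin(levels, 1L + floor((x - q[1]) / (q[2] - q[1]) * levels)),
         nrow(tile), ncol(tile))
}

glcm_matrix <- function(qtile, levels, offsets) {
  P <- matrix(0, levels, levels)
  nr <- nrow(qtile); nc <- ncol(qtile)
  for (off in offsets) {
    dr <- off[1]; dc <- off[2]
    r1 <- max(1, 1 - dr):min(nr, nr - dr)
    c1 <- max(1, 1 - dc):min(nc, nc - dc)
    a <- qtile[r1, c1, drop = FALSE]
    b <- qtile[r1 + dr, c1 + dc, drop = FALSE]
    t <- table(factor(a, levels = seq_len(levels)),
               factor(b, levels = seq_len(levels)))
    P <- P + t + t(t)   # symmetric accumulation
  }
  P / sum(P)
}

#' Haralick texture features of a tile
#'
#' Gray-level co-occurrence features over a symmetric, normalized matrix
#' averaged across the configured offsets: contrast, energy (angular second
#' moment), homogeneity (inverse difference moment), correlation, and
#' entropy (bits).  A constant tile yields energy 1, contrast 0, entropy 0
#' and correlation defined as 0.
#'
#' @param tile numeric matrix.
#' @param config a [tile_config()].
#' @return named numeric vector `glcm_*`.
#' @export
texture_features <- function(tile, config = tile_config()) {
  L <- config$glcm_levels
  q <- quantize_tile(tile, L)
  P <- glcm_matrix(q, L, config$glcm_offsets)
  i <- matrix(rep(seq_len(L), L), L)
  j <- t(i)
  mu_i <- sum(i * P); mu_j <- sum(j * P)
  s_i <- sqrt(sum((i - mu_i)^2 * P)); s_j <- sqrt(sum((j - mu_j)^2 * P))
  pos <- P > 0
  c(glcm_contrast = sum((i - j)^2 * P),
    glcm_energy = sum(P^2),
    glcm_homogeneity = sum(P / (1 + abs(i - j))),
    glcm_correlation = if (s_i > 0 && s_j > 0)
      sum((i - mu_i) * (j - mu_j) * P) / (s_i * s_j) else 0,
    glcm_entropy = -sum(P[pos] * log2(P[pos])))
}

# --- fractal / granulometry ---------------------------------------------

# Local binarization of a tile.  The default "mad" rule takes foreground
# as pixels above median + k * MAD: robust on tiles that are mostly
# background or cytoplasm, and (unlike a forced Otsu split) it leaves
# noise-only tiles nearly empty instead of turning noise into speckle.
# Returns NULL for a degenerate (constant) tile.
binarize_tile <- function(tile, config) {
  rng <- diff(range(tile))
  if (rng < .Machine$double.eps * 100) return(NULL)
  if (config$binarize == "otsu") {
    thr <- otsu_threshold(tile)
    if (is.na(thr)) return(NULL)
    return(tile > thr)
  }
  med <- stats::median(tile)
  madv <- stats::mad(tile)
  if (madv == 0) {   # more than half the tile is one flat level
    thr <- otsu_threshold(tile)
    if (is.na(thr)) return(NULL)
    return(tile > thr)
  }
  tile > med + config$mad_k * madv
}

# Box count at integer box size s (pixels), padding partial boxes.
box_count <- function(bin, s) {
  nr <- nrow(bin); nc <- ncol(bin)
  ri <- (seq_len(nr) - 1L) %/% s
  ci <- (seq_len(nc) - 1L) %/% s
  occ <- rowsum(bin + 0, ri)
  occ <- t(rowsum(t(occ), ci))
  sum(occ > 0)
}

box_dimension <- function(bin, sizes) {
  if (sum(bin) == 0) return(NA_real_)
  # crop to the foreground bounding box so box sizes scale with the
  # structure, not the field it sits in
  rr <- range(which(rowSums(bin) > 0)); cc <- range(which(colSums(bin) > 0))
  bin <- bin[rr[1]:rr[2], cc[1]:cc[2], drop = FALSE]
  sizes <- unique(sizes[sizes >= 1 & sizes <= max(dim(bin)) / 2])
  if (length(sizes) < 2) return(NA_real_)
  N <- vapply(sizes, function(s) box_count(bin, s), numeric(1))
  keep <- N > 0
  if (sum(keep) < 2) return(NA_real_)
  -stats::coef(stats::lm(log(N[keep]) ~ log(sizes[keep])))[[2]]
}

#' Box-counting fractal dimension of a binary image
#'
#' Slope of log N(eps) against log eps.  Default box sizes are the
#' divisors of the image side (exact tiling, so no partial-box bias, which
#' matters on triadic fixtures); when fewer than four divisors fall in
#' range, a dyadic ladder is used instead.
#'
#' @param bin binary matrix.
#' @param sizes box sizes in pixels; NULL for the default ladder.
#' @return estimated dimension.
#' @export
box_counting_dimension <- function(bin, sizes = NULL) {
  bin <- bin > 0
  if (is.null(sizes)) {
    if (sum(bin) == 0) return(NA_real_)
    rr <- range(which(rowSums(bin) > 0)); cc <- range(which(colSums(bin) > 0))
    n <- max(rr[2] - rr[1], cc[2] - cc[1]) + 1L
    div <- which(n %% seq_len(max(1, n %/% 3)) == 0)
    sizes <- if (length(div) >= 4) div else 2^(0:max(1, floor(log2(n / 2))))
  }
  box_dimension(bin, sizes)
}

disc_brush <- function(d_px) EBImage::makeBrush(max(3L, 2L * floor(d_px / 2) + 1L), "disc")

# Line structuring element of length L_px at the given angle (degrees).
line_brush <- function(L_px, angle_deg) {
  L <- max(3L, as.integer(L_px))
  half <- (L - 1) / 2
  t <- seq(-half, half, by = 0.5)
  th <- angle_deg * pi / 180
  r <- round(t * sin(th)); c <- round(t * cos(th))
  hr <- max(abs(r)); hc <- max(abs(c))
  m <- matrix(0, 2 * hr + 1, 2 * hc + 1)
  m[cbind(r + hr + 1, c + hc + 1)] <- 1
  m
}

opened_area <- function(bin, brush) sum(EBImage::opening(bin + 0, brush) > 0)

#' Fractal and morphological pattern features of a tile
#'
#' The tile is binarized by Otsu's rule (bright = high refractive index).
#' Features: the global box-counting dimension over dyadic scales;
#' band-limited box dimensions using only box sizes inside the configured
#' micrometre bands (5-9 um and 17-23 um capture the oblong directional
#' cells); a curvilinear pattern score for structures with curvature
#' diameter 4-8 um (area surviving a length-matched line opening in its
#' best orientation but removed by the width-matched disk opening); and a
#' circular pattern score (granulometry: area fraction surviving a disk
#' opening of 34-38 um^2, matching lipid-droplet cross-sections).
#' An empty binarization yields all-zero features with attribute
#' `empty = TRUE`.
#'
#' @param tile numeric matrix.
#' @param pixel_size micrometres per pixel.
#' @param config a [tile_config()].
#' @return named numeric vector `fractal_*`, `curve_pattern_4_8um`,
#'   `circle_pattern_34_38um2`.
#' @export
fractal_features <- function(tile, pixel_size, config = tile_config()) {
  bin <- binarize_tile(tile, config)
  empty <- is.null(bin) || sum(bin) == 0
  if (is.null(bin)) bin <- matrix(FALSE, nrow(tile), ncol(tile))
  nm <- c("fractal_boxdim_global",
          paste0("fractal_", names(config$fractal_bands)),
          "curve_pattern_4_8um", "circle_pattern_34_38um2")
  if (empty) {
    out <- stats::setNames(numeric(length(nm)), nm)
    attr(out, "empty") <- TRUE
    return(out)
  }
  npx <- length(bin)
  dims <- box_counting_dimension(bin)
  bands <- vapply(config$fractal_bands, function(b) {
    lo <- max(1, floor(b[1] / pixel_size))
    hi <- ceiling(b[2] / pixel_size)
    if (hi <= lo) hi <- lo + 1
    d <- box_dimension(bin, lo:hi)
    if (is.na(d)) 0 else d
  }, numeric(1))
  # curvilinear score
  d_mid <- mean(config$curve_band_um)
  L_px <- max(3L, round(d_mid / pixel_size))
  line_max <- matrix(0, nrow(bin), ncol(bin))
  for (ang in c(0, 45, 90, 135))
    line_max <- pmax(line_max, EBImage::opening(bin + 0, line_brush(L_px, ang)))
  disc_open <- EBImage::opening(bin + 0, disc_brush(d_mid / pixel_size))
  curve <- max(0, sum(line_max > 0) - sum(disc_open > 0)) / npx
  # circular score: granulometry at the band's mid disk area
  a_mid <- mean(config$circle_band_um2)
  d_circ <- 2 * sqrt(a_mid / pi)
  circ <- opened_area(bin, disc_brush(d_circ / pixel_size)) / npx
  out <- c(if (is.na(dims)) 0 else dims, bands, curve, circ)
  names(out) <- nm
  attr(out, "empty") <- FALSE
  out
}

# --- Fourier spectrum ----------------------------------------------------

hann2d <- function(n) {
  w <- 0.5 * (1 - cos(2 * pi * (seq_len(n) - 1) / (n - 1)))
  outer(w, w)
}

#' Fourier-spectrum features of a tile
#'
#' The tile is mean-subtracted and Hann-windowed.  Radial band powers
#' partition the spectrum by spatial period (> 23, 17-23, 9-17, 5-9 and
#' < 5 um), normalized so they sum to the total variance of the windowed
#' tile (Parseval).  `fourier_anisotropy` is the resultant length of the
#' power-weighted, angle-doubled orientation distribution (0 isotropic,
#' 1 single orientation); the dominant radial frequency (cycles/um) and
#' orientation (degrees, normal to wave crests) are also reported.
#'
#' @param tile numeric matrix (square).
#' @param pixel_size micrometres per pixel.
#' @param config a [tile_config()].
#' @return named numeric vector `fourier_*`.
#' @export
fourier_features <- function(tile, pixel_size, config = tile_config()) {
  n <- nrow(tile)
  wt <- (tile - mean(tile)) * hann2d(n)
  F2 <- Mod(stats::fft(wt))^2
  npx <- length(wt)
  fy <- fft_freq(nrow(wt)) / pixel_size
  fx <- fft_freq(ncol(wt)) / pixel_size
  KX <- matrix(rep(fx, each = nrow(wt)), nrow(wt))
  KY <- matrix(rep(fy, ncol(wt)), nrow(wt))
  kmag <- sqrt(KX^2 + KY^2)
  edges_um <- c(Inf, 23, 17, 9, 5, 0)   # periods
  nmz <- c("fourier_power_gt23um", "fourier_power_17_23um",
           "fourier_power_9_17um", "fourier_power_5_9um",
           "fourier_power_lt5um")
  bands <- numeric(5)
  for (b in seq_len(5)) {
    lo <- if (is.infinite(edges_um[b])) 0 else 1 / edges_um[b]
    hi <- if (edges_um[b + 1] == 0) Inf else 1 / edges_um[b + 1]
    sel <- kmag >= lo & kmag < hi
    bands[b] <- sum(F2[sel]) / npx^2
  }
  tot <- sum(F2) / npx^2
  nz <- kmag > 0
  w <- F2[nz]
  th <- atan2(KY[nz], KX[nz])
  aniso <- if (sum(w) > 0)
    Mod(sum(w * exp(2i * th))) / sum(w) else 0
  peak <- which.max(F2 * nz)
  c(stats::setNames(bands, nmz),
    fourier_total_power = tot,
    fourier_anisotropy = aniso,
    fourier_peak_freq = kmag[peak],
    fourier_peak_orientation = (atan2(KY[peak], KX[peak]) * 180 / pi) %% 180)
}

# --- autocorrelation -----------------------------------------------------

#' Autocorrelation features of a tile
#'
#' Normalized autocorrelation via the Fourier method (unit value at zero
#' lag).  The correlation length is the radius (um) where the azimuthally
#' averaged autocorrelation first falls below 1/e (linear interpolation);
#' anisotropy is 1 - (minor/major radius) of the 1/e contour estimated
#' from directional profiles.  A constant tile yields zeros with attribute
#' `empty = TRUE`.
#'
#' @param tile numeric matrix.
#' @param pixel_size micrometres per pixel.
#' @param config a [tile_config()].
#' @return named numeric vector `autocorr_*`.
#' @export
autocorr_features <- function(tile, pixel_size, config = tile_config()) {
  nm <- c("autocorr_length_um", "autocorr_anisotropy")
  v <- stats::var(as.vector(tile))
  if (v <= .Machine$double.eps * 100) {
    out <- stats::setNames(numeric(2), nm)
    attr(out, "empty") <- TRUE
    return(out)
  }
  x <- tile - mean(tile)
  ac <- Re(ifft2(Mod(stats::fft(x))^2))
  ac <- ac / ac[1, 1]
  nr <- nrow(ac); nc <- ncol(ac)
  acs <- ac[c((nr %/% 2 + 1):nr, 1:(nr %/% 2)), c((nc %/% 2 + 1):nc, 1:(nc %/% 2))]
  cy <- nr %/% 2 + 1L; cx <- nc %/% 2 + 1L
  rmax <- min(nr, nc) %/% 2 - 1L
  prof <- radial_profile(acs, cx, cy, rmax)
  len_px <- first_crossing(prof, exp(-1))
  # anisotropy from the moment ellipse of the supra-1/e region around the
  # center (1 - minor/major axis ratio of the 1/e contour)
  idx <- which(acs >= exp(-1), arr.ind = TRUE)
  keep <- sqrt((idx[, 1] - cy)^2 + (idx[, 2] - cx)^2) <= rmax
  idx <- idx[keep, , drop = FALSE]
  aniso <- 0
  if (nrow(idx) > 1) {
    y <- idx[, 1]; x2 <- idx[, 2]
    mxx <- mean((x2 - mean(x2))^2) + 1 / 12
    myy <- mean((y - mean(y))^2) + 1 / 12
    mxy <- mean((x2 - mean(x2)) * (y - mean(y)))
    tr <- mxx + myy; dd <- sqrt(max(0, (mxx - myy)^2 + 4 * mxy^2))
    aniso <- 1 - sqrt(max(0, (tr - dd)) / (tr + dd))
  }
  out <- c(autocorr_length_um = len_px * pixel_size,
           autocorr_anisotropy = aniso)
  attr(out, "empty") <- FALSE
  out
}

first_crossing <- function(profile, level) {
  idx <- which(profile < level)[1]
  if (is.na(idx)) return(length(profile) - 1)
  if (idx == 1) return(0)
  r1 <- idx - 2; p1 <- profile[idx - 1]; p2 <- profile[idx]
  r1 + (p1 - level) / (p1 - p2)
}

bilinear <- function(m, r, c) {
  r0 <- floor(r); c0 <- floor(c)
  if (r0 < 1 || c0 < 1 || r0 + 1 > nrow(m) || c0 + 1 > ncol(m)) return(NA_real_)
  fr <- r - r0; fc <- c - c0
  m[r0, c0] * (1 - fr) * (1 - fc) + m[r0 + 1, c0] * fr * (1 - fc) +
    m[r0, c0 + 1] * (1 - fr) * fc + m[r0 + 1, c0 + 1] * fr * fc
}

# --- feature table -------------------------------------------------------

tile_feature_vector <- function(tile, pixel_size, config) {
  out <- numeric(0)
  if ("glcm" %in% config$families)
    out <- c(out, texture_features(tile, config))
  if ("fractal" %in% config$families)
    out <- c(out, fractal_features(tile, pixel_size, config))
  if ("fourier" %in% config$families)
    out <- c(out, fourier_features(tile, pixel_size, config))
  if ("autocorr" %in% config$families)
    out <- c(out, autocorr_features(tile, pixel_size, config))
  out
}

#' Extract a tiles-by-features table from a set of images
#'
#' @param images list of numeric matrices (phase or refractive-index
#'   images), all at the same pixel size.
#' @param metadata data.frame with one row per image (e.g. organoid, group,
#'   week); replicated across that image's tiles.
#' @param pixel_size micrometres per pixel (scalar; mixed pixel sizes are
#'   an error).
#' @param config a [tile_config()].
#' @return data.frame of class `feature_table`: metadata columns, `image`,
#'   `tile`, then one column per feature, in deterministic order.
#' @export
extract_feature_table <- function(images, metadata = NULL, pixel_size,
                                  config = tile_config()) {
  if (length(pixel_size) != 1)
    stopf("images with mixed pixel sizes are not supported; resample first")
  if (!is.null(metadata) && nrow(metadata) != length(images))
    stopf("metadata must have one row per image")
  rows <- vector("list", length(images))
  for (ii in seq_along(images)) {
    tl <- tile_image(images[[ii]], pixel_size, config$tile_size_um,
                     config$stride_um)
    fv <- t(vapply(tl$tiles, tile_feature_vector, pixel_size = pixel_size,
                   config = config,
                   FUN.VALUE = tile_feature_vector(tl$tiles[[1]], pixel_size,
                                                   config)))
    df <- as.data.frame(fv)
    base <- data.frame(image = ii, tile = seq_len(nrow(df)))
    if (!is.null(metadata))
      base <- cbind(metadata[rep(ii, nrow(df)), , drop = FALSE], base)
    rownames(base) <- NULL
    rows[[ii]] <- cbind(base, df)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("feature_table", "data.frame")
  out
}

#' Names of the feature columns of a feature table
#' @param ft a `feature_table`.
#' @return character vector.
#' @export
feature_names <- function(ft) {
  meta <- c("organoid", "group", "week", "image", "tile",
            "gt_directional_density", "gt_droplet_fraction",
            "gt_rosette_count", "realized_droplet_fraction")
  setdiff(names(ft), meta)
}
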