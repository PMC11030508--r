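# Compartment label codes used in every ground-truth phantom.
LABELS <- c(background = 0L, cytoplasm = 1L, rosette = 2L, lumen = 3L,
            droplet = 4L, directional_cell = 5L, fissure = 6L)

#' Specification of a synthetic organoid section phantom
#'
#' Describes one two-dimensional organoid section: an elliptical organoid
#' body containing neural rosettes (radial cell arrangements around a
#' lumen), surface fissures flanked by elongated, aligned "directional"
#' cells, and high-refractive-index lipid droplets.  The phantom is the
#' ground truth for the whole analysis pipeline: every placed structure is
#' recorded in a label mask, so downstream measurements can be checked
#' against construction.
#'
#' @param image_size side of the square image, pixels.
#' @param pixel_size pixel pitch, micrometres per pixel.
#' @param organoid_axes ellipse semi-axes of the organoid body, micrometres.
#' @param rosette_count number of rosettes to place.
#' @param rosette_radius_range rosette radius range, micrometres.
#' @param lumen_offset_fraction lumen centroid offset as a fraction of the
#'   available in-rosette travel; 0 gives a concentric lumen.
#' @param fissure_count number of fissure polylines.
#' @param directional_cell_density directional cells per square millimetre
#'   within the band flanking each fissure.
#' @param directional_cell_aspect length/width aspect ratio of directional
#'   cells (>= 1).
#' @param directional_cell_length directional cell long axis, micrometres.
#' @param droplet_area_fraction target lipid-droplet area as a fraction of
#'   organoid area, in [0, 0.3].
#' @param droplet_diameter_range droplet diameter range, micrometres.
#' @param compartment_ri named refractive indices for medium, cytoplasm,
#'   nucleus-dense tissue and lipid droplets.  The medium default 1.3440 is
#'   the refractive index of the scattering medium used for imaging; the
#'   droplet default lies above the 1.46 segmentation threshold.
#' @param seed integer seed; identical spec + seed gives a bit-identical
#'   phantom.
#' @return an object of class `phantom_spec`.
#' @export
phantom_spec <- function(image_size = 512, pixel_size = 1,
                         organoid_axes = c(200, 160),
                         rosette_count = 5, rosette_radius_range = c(20, 35),
                         lumen_offset_fraction = 0.2,
                         fissure_count = 2,
                         directional_cell_density = 4000,
                         directional_cell_aspect = 2.5,
                         directional_cell_length = 8,
                         droplet_area_fraction = 0.02,
                         droplet_diameter_range = c(4, 8),
                         compartment_ri = c(medium = 1.3440, cytoplasm = 1.370,
                                            nucleus = 1.390, droplet = 1.500),
                         seed = 1L) {
  if (pixel_size <= 0) stopf("pixel_size must be positive")
  if (droplet_area_fraction < 0 || droplet_area_fraction > 0.3)
    stopf("droplet_area_fraction must lie in [0, 0.3]")
  if (lumen_offset_fraction < 0 || lumen_offset_fraction >= 1)
    stopf("lumen_offset_fraction must lie in [0, 1)")
  if (directional_cell_aspect < 1) stopf("directional_cell_aspect must be >= 1")
  need <- c("medium", "cytoplasm", "nucleus", "droplet")
  if (!all(need %in% names(compartment_ri)))
    stopf("compartment_ri must name %s", paste(need, collapse = ", "))
  if (compartment_ri["droplet"] <= 1.46)
    stopf("droplet refractive index must lie strictly above the 1.46 segmentation threshold")
  if (compartment_ri["medium"] >= 1.46)
    stopf("medium refractive index must lie below the 1.46 segmentation threshold")
  structure(list(
    image_size = as.integer(image_size), pixel_size = pixel_size,
    organoid_axes = organoid_axes, rosette_count = as.integer(rosette_count),
    rosette_radius_range = rosette_radius_range,
    lumen_offset_fraction = lumen_offset_fraction,
    fissure_count = as.integer(fissure_count),
    directional_cell_density = directional_cell_density,
    directional_cell_aspect = directional_cell_aspect,
    directional_cell_length = directional_cell_length,
    droplet_area_fraction = droplet_area_fraction,
    droplet_diameter_range = droplet_diameter_range,
    compartment_ri = compartment_ri, seed = as.integer(seed)),
    class = "phantom_spec")
}

#' Generate a ground-truth organoid phantom
#'
#' Rasterizes the structures described by a [phantom_spec()] into a
#' compartment label mask and the corresponding refractive-index map.
#' Rosette interiors and directional cells take the nucleus-dense RI;
#' lumens and fissure clefts are fluid-filled at the medium RI.
#'
#' @param spec a [phantom_spec()].
#' @return an object of class `organoid_phantom` with elements `ri_map`,
#'   `labels` (integer compartment codes, see `LABELS`), `spec`, `rosettes`
#'   (one row per placed rosette), `fissures`, `droplet_fraction` (realized
#'   droplet area fraction) and `organoid_px`.
#' @export
generate_organoid_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  with_seed(spec$seed, .generate_phantom_impl(spec))
}

.generate_phantom_impl <- function(spec) {
  n <- spec$image_size
  ps <- spec$pixel_size
  a0 <- spec$organoid_axes[1] / ps
  b0 <- spec$organoid_axes[2] / ps
  if (2 * a0 > n - 4 || 2 * b0 > n - 4)
    stopf("organoid (%.0f x %.0f px) does not fit the %d px field of view",
          2 * a0, 2 * b0, n)
  c0 <- (n + 1) / 2
  labels <- matrix(LABELS["background"], n, n)
  labels <- draw_ellipse(labels, LABELS["cytoplasm"], c0, c0, a0, b0)
  organoid_px <- sum(labels > 0)

  # rosettes: non-overlapping disks fully inside the organoid
  rosettes <- NULL
  if (spec$rosette_count > 0) {
    placed <- data.frame(cx = numeric(0), cy = numeric(0), r = numeric(0),
                         lx = numeric(0), ly = numeric(0), lr = numeric(0))
    for (i in seq_len(spec$rosette_count)) {
      ok <- FALSE
      for (try in seq_len(800)) {
        r <- stats::runif(1, spec$rosette_radius_range[1], spec$rosette_radius_range[2]) / ps
        sa <- max(a0 - r - 2, 1); sb <- max(b0 - r - 2, 1)
        th <- stats::runif(1, 0, 2 * pi); rad <- sqrt(stats::runif(1))
        cx <- c0 + sa * rad * cos(th); cy <- c0 + sb * rad * sin(th)
        if (((cx - c0) / sa)^2 + ((cy - c0) / sb)^2 > 1) next
        if (nrow(placed) &&
            any(sqrt((placed$cx - cx)^2 + (placed$cy - cy)^2) < placed$r + r + 3 / ps)) next
        ok <- TRUE; break
      }
      if (!ok)
        stopf("could not place rosette %d of %d: requested rosette density exceeds organoid capacity",
              i, spec$rosette_count)
      lr <- r / 3
      maxoff <- max(r - lr - max(1, 1 / ps), 0)
      off <- spec$lumen_offset_fraction * maxoff
      phi <- stats::runif(1, 0, 2 * pi)
      lx <- cx + off * cos(phi); ly <- cy + off * sin(phi)
      labels <- draw_ellipse(labels, LABELS["rosette"], cx, cy, r, r,
                             over = LABELS["cytoplasm"])
      labels <- draw_ellipse(labels, LABELS["lumen"], lx, ly, lr, lr,
                             over = LABELS["rosette"])
      placed <- rbind(placed, data.frame(cx = cx, cy = cy, r = r,
                                         lx = lx, ly = ly, lr = lr))
    }
    rosettes <- placed
  }

  # fissures: quadratic Bezier chords; directional cells flank them
  fissures <- list()
  if (spec$fissure_count > 0) {
    for (f in seq_len(spec$fissure_count)) {
      th <- stats::runif(1, 0, pi)
      s <- 0.85
      p0 <- c(c0 - s * a0 * cos(th), c0 - s * b0 * sin(th))
      p2 <- c(c0 + s * a0 * cos(th), c0 + s * b0 * sin(th))
      mid <- (p0 + p2) / 2
      len <- sqrt(sum((p2 - p0)^2))
      nrm <- c(-(p2 - p0)[2], (p2 - p0)[1]) / len
      p1 <- mid + nrm * stats::runif(1, -0.25, 0.25) * len
      t <- seq(0, 1, length.out = max(32, round(2 * len)))
      px <- (1 - t)^2 * p0[1] + 2 * (1 - t) * t * p1[1] + t^2 * p2[1]
      py <- (1 - t)^2 * p0[2] + 2 * (1 - t) * t * p1[2] + t^2 * p2[2]
      tx <- 2 * (1 - t) * (p1[1] - p0[1]) + 2 * t * (p2[1] - p1[1])
      ty <- 2 * (1 - t) * (p1[2] - p0[2]) + 2 * t * (p2[2] - p1[2])
      ang <- atan2(ty, tx)
      inside <- ((px - c0) / (a0 - 1))^2 + ((py - c0) / (b0 - 1))^2 <= 1
      w <- max(0.75, 1.5 / ps / 2)
      for (j in which(inside))
        labels <- draw_ellipse(labels, LABELS["fissure"], px[j], py[j], w, w,
                               over = LABELS["cytoplasm"])
      fissures[[f]] <- list(x = px[inside], y = py[inside], angle = ang[inside])
    }
    # directional cells within a 12 um band either side of each fissure
    band_um <- 12
    ca <- spec$directional_cell_length / 2 / ps
    cb <- ca / spec$directional_cell_aspect
    for (f in fissures) {
      npts <- length(f$x)
      if (npts < 2) next
      seg <- sqrt(diff(f$x)^2 + diff(f$y)^2)
      len_um <- sum(seg) * ps
      ncell <- round(spec$directional_cell_density * (2 * band_um * len_um) / 1e6)
      if (ncell < 1) next
      idx <- sample.int(npts, ncell, replace = TRUE)
      side <- sample(c(-1, 1), ncell, replace = TRUE)
      dist <- stats::runif(ncell, 2, band_um) / ps
      jit <- stats::rnorm(ncell, 0, 8 * pi / 180)
      for (k in seq_len(ncell)) {
        aa <- f$angle[idx[k]]
        cx <- f$x[idx[k]] - side[k] * sin(aa) * dist[k]
        cy <- f$y[idx[k]] + side[k] * cos(aa) * dist[k]
        if (((cx - c0) / a0)^2 + ((cy - c0) / b0)^2 > 1) next
        labels <- draw_ellipse(labels, LABELS["directional_cell"], cx, cy,
                               ca, cb, aa + jit[k], over = LABELS["cytoplasm"])
      }
    }
  }

  # droplets: accumulate painted pixels until the target fraction is met;
  # the last droplets are sized to the remaining area for accurate fractions
  droplet_px <- 0L
  if (spec$droplet_area_fraction > 0) {
    target <- spec$droplet_area_fraction * organoid_px
    dmin <- spec$droplet_diameter_range[1] / ps
    dmax <- spec$droplet_diameter_range[2] / ps
    mean_area <- pi * ((dmin + dmax) / 4)^2
    attempts <- 0L
    while (target - droplet_px > max(4, 0.01 * target)) {
      attempts <- attempts + 1L
      if (attempts > 40000L)
        stopf("could not reach droplet area fraction %.3f: organoid area exhausted",
              spec$droplet_area_fraction)
      remaining <- target - droplet_px
      r <- if (remaining >= mean_area) stats::runif(1, dmin, dmax) / 2
           else max(1, min(sqrt(remaining / pi), dmax / 2))
      th <- stats::runif(1, 0, 2 * pi); rad <- sqrt(stats::runif(1))
      sa <- max(a0 - r - 1, 1); sb <- max(b0 - r - 1, 1)
      cx <- c0 + sa * rad * cos(th); cy <- c0 + sb * rad * sin(th)
      before <- droplet_px
      labels2 <- draw_ellipse(labels, LABELS["droplet"], cx, cy, r, r,
                              over = LABELS["cytoplasm"])
      gained <- sum(labels2 == LABELS["droplet"]) - before
      if (gained > 0) { labels <- labels2; droplet_px <- before + gained }
    }
  }

  ri <- spec$compartment_ri
  ri_by_code <- c(ri["medium"], ri["cytoplasm"], ri["nucleus"], ri["medium"],
                  ri["droplet"], ri["nucleus"], ri["medium"])
  ri_map <- matrix(ri_by_code[labels + 1L], n, n)

  structure(list(ri_map = ri_map, labels = labels, spec = spec,
                 rosettes = rosettes, fissures = fissures,
                 droplet_fraction = droplet_px / organoid_px,
                 organoid_px = organoid_px),
            class = "organoid_phantom")
}

#' Organoid body mask of a phantom
#' @param phantom an `organoid_phantom`.
#' @return logical matrix, TRUE inside the organoid.
#' @export
organoid_mask <- function(phantom) phantom$labels != LABELS["background"]

#' @export
print.organoid_phantom <- function(x, ...) {
  s <- x$spec
  cat(sprintf("organoid phantom: %d x %d px @ %.3g um/px\n", s$image_size,
              s$image_size, s$pixel_size))
  cat(sprintf("  rosettes: %d, fissures: %d, droplet fraction: %.4f (target %.4f)\n",
              if (is.null(x$rosettes)) 0L else nrow(x$rosettes),
              length(x$fissures), x$droplet_fraction, s$droplet_area_fraction))
  cat(sprintf("  RI: medium %.4f, droplet %.3f\n",
              s$compartment_ri["medium"], s$compartment_ri["droplet"]))
  invisible(x)
}

#' Deterministic binary fixtures with known box-counting dimension
#'
#' `filled_square` (dimension 2), `line` (dimension 1) and
#' `sierpinski_carpet` (dimension log 8 / log 3 = 1.8928) fixtures used to
#' calibrate the fractal feature extractor.
#'
#' @param kind one of `"filled_square"`, `"line"`, `"sierpinski_carpet"`.
#' @param size image side in pixels; must be a power of 3 for the carpet.
#' @return binary matrix.
#' @export
make_fractal_fixture <- function(kind = c("filled_square", "line", "sierpinski_carpet"),
                                 size = 243) {
  kind <- match.arg(kind)
  size <- as.integer(size)
  if (size < 3) stopf("size must be at least 3")
  if (kind == "filled_square") return(matrix(1L, size, size))
  if (kind == "line") {
    m <- matrix(0L, size, size)
    m[size %/% 2, ] <- 1L
    return(m)
  }
  k <- round(log(size) / log(3))
  if (3^k != size) stopf("sierpinski_carpet requires size = 3^k, got %d", size)
  m <- matrix(1L, 1, 1)
  cell <- matrix(c(1, 1, 1, 1, 0, 1, 1, 1, 1), 3, 3)
  for (i in seq_len(k)) m <- kronecker(m, cell)
  storage.mode(m) <- "integer"
  m
}
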