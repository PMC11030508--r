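# Quick-look raster displays for phantoms, phase and RI maps.

img_show <- function(m, main, col = grDevices::gray.colors(256)) {
  graphics::image(t(m[nrow(m):1, , drop = FALSE]), axes = FALSE, asp = 1,
                  col = col, main = main, useRaster = TRUE)
}

#' @export
plot.organoid_phantom <- function(x, what = c("labels", "ri"), ...) {
  what <- match.arg(what)
  if (what == "labels")
    img_show(x$labels, "phantom compartments",
             col = c("black", "gray40", "orchid", "white", "yellow",
                     "skyblue", "red"))
  else img_show(x$ri_map, "refractive index")
  invisible(x)
}

#' @export
plot.phase_map <- function(x, ...) {
  img_show(x$phase, sprintf("phase (rad), dz = %.2g um", x$dz_um))
  invisible(x)
}

#' @export
plot.high_ri_result <- function(x, ...) {
  img_show(x$mask + 0, sprintf("high-RI mask (fraction %.3f)", x$area_fraction))
  invisible(x)
}
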