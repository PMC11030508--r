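# qOBM image formation and quantitative phase reconstruction.
#
# Four LED sources arranged 90 degrees apart give two opposing pairs along
# orthogonal axes.  Subtracting opposing frames forms differential phase
# contrast (DPC) images; DPC relates to sample phase through an
# antisymmetric phase transfer function, inverted here by Tikhonov-
# regularized Fourier deconvolution.

#' Parametric phase transfer model for DPC imaging
#'
#' The per-axis transfer function is
#' \deqn{H_j(k) = i \, g \, (\hat s_j \cdot \hat k) \, A(|k|)}
#' with \eqn{\hat s_j} the source obliquity axis, \eqn{g} a gain in
#' rad^-1, and \eqn{A} a radial low-pass envelope equal to 1 at DC with a
#' hard cutoff at the partially-coherent limit 2 NA / lambda.  H is purely
#' imaginary and odd in frequency, so its impulse response is real, and
#' H(0) = 0: DPC carries no information about the phase offset.
#'
#' @param na numerical aperture of the objective (default 0.45, 20X).
#' @param wavelength_nm illumination wavelength, nanometres (default 720).
#' @param gain DPC contrast per radian of phase, rad^-1.
#' @param envelope radial envelope shape; `"cos2"` is a raised-cosine
#'   falling from 1 at DC to 0 at the cutoff.
#' @param cutoff_scale multiplies the 2 NA / lambda cutoff; used to emulate
#'   model mismatch between instrument and reconstruction.
#' @return object of class `phase_transfer_model`.
#' @export
phase_transfer_model <- function(na = 0.45, wavelength_nm = 720, gain = 0.25,
                                 envelope = "cos2", cutoff_scale = 1) {
  stopifnot(na > 0, wavelength_nm > 0, gain > 0, cutoff_scale > 0)
  structure(list(na = na, wavelength_nm = wavelength_nm, gain = gain,
                 envelope = envelope, cutoff_scale = cutoff_scale),
            class = "phase_transfer_model")
}

#' Evaluate the transfer function pair on an image frequency grid
#'
#' @param model a [phase_transfer_model()].
#' @param dim image dimensions `c(nrow, ncol)`.
#' @param pixel_size micrometres per pixel.
#' @return list with complex matrices `Hx`, `Hy` (unshifted FFT layout) and
#'   the frequency magnitude grid `kmag` (cycles/um).
#' @export
build_transfer_function <- function(model, dim, pixel_size) {
  if (pixel_size <= 0) stopf("pixel_size must be positive")
  nr <- dim[1]; nc <- dim[2]
  fy <- fft_freq(nr) / pixel_size
  fx <- fft_freq(nc) / pixel_size
  KX <- matrix(rep(fx, each = nr), nr)
  KY <- matrix(rep(fy, nc), nr)
  kmag <- sqrt(KX^2 + KY^2)
  kc <- model$cutoff_scale * 2 * model$na / (model$wavelength_nm / 1000)
  A <- matrix(0, nr, nc)
  inb <- kmag < kc
  A[inb] <- cos(pi * kmag[inb] / (2 * kc))^2
  safe <- kmag
  safe[kmag == 0] <- 1
  Hx <- 1i * model$gain * (KX / safe) * A
  Hy <- 1i * model$gain * (KY / safe) * A
  Hx[kmag == 0] <- 0i
  Hy[kmag == 0] <- 0i
  # the Nyquist bins (even dimensions) have no mirror partner; zero them so
  # H is exactly odd and its impulse response exactly real
  nyq <- abs(abs(fy) - 0.5 / pixel_size) < 1e-12
  if (any(nyq)) { Hx[nyq, ] <- 0i; Hy[nyq, ] <- 0i }
  nyqc <- abs(abs(fx) - 0.5 / pixel_size) < 1e-12
  if (any(nyqc)) { Hx[, nyqc] <- 0i; Hy[, nyqc] <- 0i }
  list(Hx = Hx, Hy = Hy, kmag = kmag)
}

#' Forward-project a phase image to its DPC pair
#'
#' Applies the transfer function in the Fourier domain; this is the forward
#' model shared by the acquisition simulator and (as its adjoint) the
#' reconstructor.
#'
#' @param phase phase image in radians (matrix or `phase_map`).
#' @param model a [phase_transfer_model()].
#' @param pixel_size micrometres per pixel (ignored if `phase` is a
#'   `phase_map`).
#' @return object of class `dpc_pair` with elements `dpc_x`, `dpc_y`,
#'   `pixel_size`.
#' @export
forward_project <- function(phase, model, pixel_size = NULL) {
  if (inherits(phase, "phase_map")) {
    pixel_size <- phase$pixel_size
    phase <- phase$phase
  }
  H <- build_transfer_function(model, dim(phase), pixel_size)
  Fp <- stats::fft(phase)
  dpc_x <- Re(ifft2(H$Hx * Fp))
  dpc_y <- Re(ifft2(H$Hy * Fp))
  structure(list(dpc_x = dpc_x, dpc_y = dpc_y, pixel_size = pixel_size),
            class = "dpc_pair")
}

#' Form differential phase contrast images from a four-frame raw set
#'
#' Per axis, DPC = (I_a - I_b) / (I_a + I_b) for the two opposing sources;
#' values lie in [-1, 1].  Pixels where the frame sum is zero are defined
#' as 0 and counted in a warning.
#'
#' @param raw a `raw_frameset` from [simulate_qobm_acquisition()] or built
#'   from measured frames via [raw_frameset()].
#' @return a `dpc_pair`.
#' @export
compute_dpc <- function(raw) {
  stopifnot(inherits(raw, "raw_frameset"))
  f <- raw$frames
  mk <- function(a, b) {
    s <- a + b
    bad <- s == 0
    s[bad] <- 1
    d <- (a - b) / s
    d[bad] <- 0
    attr(d, "zero_sum_px") <- sum(bad)
    d
  }
  dx <- mk(f[, , 1], f[, , 2])
  dy <- mk(f[, , 3], f[, , 4])
  nz <- attr(dx, "zero_sum_px") + attr(dy, "zero_sum_px")
  if (nz > 0) warnf("%d zero-sum pixels set to DPC = 0", nz)
  attr(dx, "zero_sum_px") <- attr(dy, "zero_sum_px") <- NULL
  structure(list(dpc_x = dx, dpc_y = dy, pixel_size = raw$pixel_size),
            class = "dpc_pair")
}

#' Container for a four-frame oblique-illumination acquisition
#'
#' @param frames numeric array `[rows, cols, 4]`; source order +x, -x, +y,
#'   -y.  All values must be strictly positive.
#' @param pixel_size micrometres per pixel.
#' @param wavelength_nm illumination wavelength.
#' @return object of class `raw_frameset`.
#' @export
raw_frameset <- function(frames, pixel_size, wavelength_nm = 720) {
  stopifnot(length(dim(frames)) == 3, dim(frames)[3] == 4)
  if (any(frames <= 0)) stopf("raw frames must be strictly positive")
  structure(list(frames = frames, pixel_size = pixel_size,
                 wavelength_nm = wavelength_nm),
            class = "raw_frameset")
}

#' Acquisition settings for the qOBM simulator
#'
#' @param wavelength_nm LED wavelength, nanometres.
#' @param dz_um effective optical section thickness, micrometres.
#' @param background mean background intensity of each frame.
#' @param snr_db signal-to-noise ratio in dB relative to the background
#'   level (`Inf` = noiseless additive model).
#' @param poisson also apply Poisson (shot) noise at `poisson_scale`
#'   expected counts per unit intensity.
#' @param poisson_scale counts per intensity unit when `poisson = TRUE`.
#' @param model the [phase_transfer_model()] of the instrument.
#' @return object of class `acquisition_spec`.
#' @export
acquisition_spec <- function(wavelength_nm = 720, dz_um = 2.5, background = 1,
                             snr_db = Inf, poisson = FALSE,
                             poisson_scale = 1e4,
                             model = phase_transfer_model(wavelength_nm = wavelength_nm)) {
  stopifnot(wavelength_nm > 0, dz_um > 0, background > 0)
  structure(list(wavelength_nm = wavelength_nm, dz_um = dz_um,
                 background = background, snr_db = snr_db, poisson = poisson,
                 poisson_scale = poisson_scale, model = model),
            class = "acquisition_spec")
}

#' Simulate a qOBM acquisition of a phantom
#'
#' Converts the phantom's refractive-index contrast to phase
#' (\eqn{\Delta\phi = 2\pi\,\Delta z\,\Delta n/\lambda}), forward-projects it
#' through the transfer model, and forms the four frames as
#' `background * (1 +/- DPC_axis)` plus noise.  Gaussian noise has standard
#' deviation `background / 10^(snr_db/20)`.  Non-positive intensities are
#' clipped to a small positive floor and counted in a warning.
#'
#' @param truth an `organoid_phantom` (or an `ri_map`-like matrix of
#'   refractive indices with attribute handling left to the caller).
#' @param acq an [acquisition_spec()].
#' @param seed optional seed for the noise stream.
#' @return a `raw_frameset`; the noiseless phase used is attached as
#'   attribute `"true_phase"` (a `phase_map`).
#' @export
simulate_qobm_acquisition <- function(truth, acq = acquisition_spec(), seed = NULL) {
  stopifnot(inherits(truth, "organoid_phantom"), inherits(acq, "acquisition_spec"))
  lambda_um <- acq$wavelength_nm / 1000
  n_m <- truth$spec$compartment_ri[["medium"]]
  dn <- truth$ri_map - n_m
  phase <- 2 * pi * acq$dz_um * dn / lambda_um
  ps <- truth$spec$pixel_size
  dpc <- forward_project(phase, acq$model, ps)
  bg <- acq$background
  frames <- array(0, c(nrow(phase), ncol(phase), 4))
  frames[, , 1] <- bg * (1 + dpc$dpc_x)
  frames[, , 2] <- bg * (1 - dpc$dpc_x)
  frames[, , 3] <- bg * (1 + dpc$dpc_y)
  frames[, , 4] <- bg * (1 - dpc$dpc_y)
  frames <- with_seed(seed, {
    if (is.finite(acq$snr_db)) {
      sd <- bg / 10^(acq$snr_db / 20)
      frames <- frames + stats::rnorm(length(frames), 0, sd)
    }
    if (acq$poisson)
      frames <- array(stats::rpois(length(frames),
                                   pmax(frames, 0) * acq$poisson_scale) /
                        acq$poisson_scale, dim(frames))
    frames
  })
  floor_val <- bg * 1e-6
  nclip <- sum(frames < floor_val)
  if (nclip > 0) {
    warnf("%d non-positive intensities clipped (SNR too low)", nclip)
    frames[frames < floor_val] <- floor_val
  }
  out <- raw_frameset(frames, ps, acq$wavelength_nm)
  attr(out, "true_phase") <- phase_map(phase, ps, acq$wavelength_nm, acq$dz_um)
  out
}

#' Quantitative phase map container
#'
#' @param phase phase image in radians, referenced to the medium.
#' @param pixel_size micrometres per pixel.
#' @param wavelength_nm illumination wavelength.
#' @param dz_um effective section thickness.
#' @return object of class `phase_map`.
#' @export
phase_map <- function(phase, pixel_size, wavelength_nm = 720, dz_um = 2.5) {
  stopifnot(all(is.finite(phase)))
  structure(list(phase = phase, pixel_size = pixel_size,
                 wavelength_nm = wavelength_nm, dz_um = dz_um),
            class = "phase_map")
}

#' Reconstruction settings
#'
#' @param beta Tikhonov regularization weight (> 0).
#' @param background_reference rule fixing the additive phase constant:
#'   `"border"` zeroes the median of a border band, `"none"` leaves the
#'   raw deconvolution output.
#' @param border_px width of the border band in pixels.
#' @return object of class `recon_config`.
#' @export
recon_config <- function(beta = 7e-3, background_reference = c("border", "none"),
                         border_px = 8) {
  if (beta <= 0) stopf("beta must be positive")
  structure(list(beta = beta,
                 background_reference = match.arg(background_reference),
                 border_px = as.integer(border_px)),
            class = "recon_config")
}

#' Reconstruct quantitative phase from a DPC pair
#'
#' Tikhonov-regularized least-squares deconvolution:
#' \deqn{\hat\phi = F^{-1}\!\left[\frac{\sum_j \bar H_j \, F(\mathrm{DPC}_j)}
#'   {\sum_j |H_j|^2 + \beta}\right]}
#' followed by fixing the (unobservable) additive constant with the
#' background-reference rule.
#'
#' @param dpc a `dpc_pair`.
#' @param model the [phase_transfer_model()] assumed for the instrument.
#' @param cfg a [recon_config()].
#' @param wavelength_nm,dz_um metadata stored in the result for downstream
#'   refractive-index conversion.
#' @return a `phase_map`.
#' @export
reconstruct_phase <- function(dpc, model, cfg = recon_config(),
                              wavelength_nm = model$wavelength_nm, dz_um = 2.5) {
  stopifnot(inherits(dpc, "dpc_pair"), inherits(cfg, "recon_config"))
  H <- build_transfer_function(model, dim(dpc$dpc_x), dpc$pixel_size)
  num <- Conj(H$Hx) * stats::fft(dpc$dpc_x) + Conj(H$Hy) * stats::fft(dpc$dpc_y)
  den <- Mod(H$Hx)^2 + Mod(H$Hy)^2 + cfg$beta
  phi <- Re(ifft2(num / den))
  if (cfg$background_reference == "border") {
    b <- min(cfg$border_px, floor(min(dim(phi)) / 4))
    band <- rbind(phi[seq_len(b), ], phi[nrow(phi) - seq_len(b) + 1, ],
                  t(phi[, seq_len(b)]), t(phi[, ncol(phi) - seq_len(b) + 1]))
    phi <- phi - stats::median(band)
  }
  phase_map(phi, dpc$pixel_size, wavelength_nm, dz_um)
}

#' @export
print.phase_map <- function(x, ...) {
  cat(sprintf("phase map: %d x %d px @ %.3g um/px, range [%.3f, %.3f] rad\n",
              nrow(x$phase), ncol(x$phase), x$pixel_size,
              min(x$phase), max(x$phase)))
  invisible(x)
}

#' @export
print.dpc_pair <- function(x, ...) {
  cat(sprintf("DPC pair: %d x %d px, |dpc| max %.3f\n", nrow(x$dpc_x),
              ncol(x$dpc_x), max(abs(c(x$dpc_x, x$dpc_y)))))
  invisible(x)
}
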