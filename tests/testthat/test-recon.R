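model <- phase_transfer_model()

test_that("DPC of constant frames is the normalized difference", {
  n <- 32
  frames <- array(0, c(n, n, 4))
  frames[, , 1] <- 1.2; frames[, , 2] <- 0.8
  frames[, , 3] <- 1;   frames[, , 4] <- 1
  dpc <- compute_dpc(raw_frameset(frames, 1))
  expect_equal(dpc$dpc_x, matrix(0.2, n, n))
  expect_equal(dpc$dpc_y, matrix(0, n, n))
  # swapping a pair negates its DPC exactly
  fr2 <- frames[, , c(2, 1, 3, 4)]
  dpc2 <- compute_dpc(raw_frameset(fr2, 1))
  expect_equal(dpc2$dpc_x, -dpc$dpc_x)
})

test_that("transfer function is odd, zero at DC and on the orthogonal axis", {
  H <- build_transfer_function(model, c(64, 64), 1)
  expect_identical(H$Hx[1, 1], 0 + 0i)
  expect_identical(H$Hy[1, 1], 0 + 0i)
  # Hx vanishes on the ky axis (kx = 0)
  expect_true(all(Mod(H$Hx[, 1]) == 0))
  expect_true(all(Mod(H$Hy[1, ]) == 0))
  # odd: H(-k) = -H(k); index (i, j) maps to (n-i+2, n-j+2) for i, j > 1
  n <- 64
  expect_equal(H$Hx[2:n, 2:n], -H$Hx[n:2, n:2], tolerance = 1e-12)
  expect_equal(H$Hy[2:n, 2:n], -H$Hy[n:2, n:2], tolerance = 1e-12)
  expect_true(all(Re(H$Hx) == 0))  # purely imaginary
})

test_that("forward projection of flat or constant phase is zero", {
  z <- matrix(0, 48, 48)
  expect_equal(forward_project(z, model, 1)$dpc_x, z)
  expect_equal(forward_project(z + 3.2, model, 1)$dpc_x, z, tolerance = 1e-12)
})

test_that("forward projection of a single Fourier mode has amplitude |H|", {
  n <- 64; ps <- 1
  kx_cyc <- 5 / n   # cycles per pixel
  X <- matrix(rep(0:(n - 1), each = n), n)
  phase <- cos(2 * pi * kx_cyc * X)
  dpc <- forward_project(phase, model, ps)
  H <- build_transfer_function(model, c(n, n), ps)
  # mode sits at column index 6 (kx = 5/n), row 1
  expected_amp <- Mod(H$Hx[1, 6])
  expect_equal(max(abs(dpc$dpc_x)), expected_amp, tolerance = 1e-6)
  expect_equal(max(abs(dpc$dpc_y)), 0, tolerance = 1e-12)
})

test_that("flat phantom produces equal frames and antisymmetric signal", {
  sp <- small_phantom_spec(rosette_count = 0, fissure_count = 0,
                           droplet_area_fraction = 0,
                           compartment_ri = c(medium = 1.3440, cytoplasm = 1.3440,
                                              nucleus = 1.3440, droplet = 1.461))
  ph <- generate_organoid_phantom(sp)
  raw <- simulate_qobm_acquisition(ph, acquisition_spec(snr_db = Inf))
  expect_equal(raw$frames[, , 1], raw$frames[, , 2], tolerance = 1e-12)
  raw2 <- simulate_qobm_acquisition(generate_organoid_phantom(small_phantom_spec()),
                                    acquisition_spec(snr_db = Inf))
  expect_equal(raw2$frames[, , 1] - raw2$frames[, , 2],
               -(raw2$frames[, , 2] - raw2$frames[, , 1]))
  expect_true(all(raw2$frames > 0))
})

test_that("empirical noise variance matches the configured SNR", {
  sp <- small_phantom_spec(rosette_count = 0, fissure_count = 0,
                           droplet_area_fraction = 0)
  ph <- generate_organoid_phantom(sp)
  raw <- simulate_qobm_acquisition(ph, acquisition_spec(snr_db = 20), seed = 5)
  # background corner is flat: noise sd should be bg/10 there
  corner <- raw$frames[1:30, 1:30, 1]
  expect_equal(sd(corner), 0.1, tolerance = 0.1)
})

test_that("noiseless forward-inverse round trip recovers phase to <1% RMSE", {
  ph <- generate_organoid_phantom(small_phantom_spec(seed = 2))
  raw <- simulate_qobm_acquisition(ph, acquisition_spec(snr_db = Inf))
  truth <- attr(raw, "true_phase")$phase
  rec <- reconstruct_phase(compute_dpc(raw), model,
                           recon_config(beta = 1e-6), dz_um = 2.5)
  err <- rec$phase - truth
  err <- err - mean(err)
  expect_lt(sqrt(mean(err^2)) / diff(range(truth)), 0.01)
})

test_that("adding a phase constant does not change the reconstruction", {
  set.seed(4)
  phase <- matrix(0, 64, 64)
  phase[20:40, 20:40] <- 1.5
  rec1 <- reconstruct_phase(forward_project(phase, model, 1), model,
                            recon_config(beta = 1e-6))
  rec2 <- reconstruct_phase(forward_project(phase + 2.7, model, 1), model,
                            recon_config(beta = 1e-6))
  expect_equal(rec1$phase, rec2$phase, tolerance = 1e-9)
})

test_that("reconstruction is linear in the DPC input", {
  set.seed(8)
  p1 <- matrix(rnorm(32 * 32), 32); p2 <- matrix(rnorm(32 * 32), 32)
  d1 <- forward_project(p1, model, 1); d2 <- forward_project(p2, model, 1)
  mix <- d1
  mix$dpc_x <- 2 * d1$dpc_x - 0.5 * d2$dpc_x
  mix$dpc_y <- 2 * d1$dpc_y - 0.5 * d2$dpc_y
  cfg <- recon_config(beta = 1e-4, background_reference = "none")
  r_mix <- reconstruct_phase(mix, model, cfg)$phase
  r_lin <- 2 * reconstruct_phase(d1, model, cfg)$phase -
    0.5 * reconstruct_phase(d2, model, cfg)$phase
  expect_equal(r_mix, r_lin, tolerance = 1e-10)
})

test_that("round-trip error grows monotonically with regularization", {
  ph <- generate_organoid_phantom(small_phantom_spec(seed = 6))
  raw <- simulate_qobm_acquisition(ph, acquisition_spec(snr_db = Inf))
  truth <- attr(raw, "true_phase")$phase
  dpc <- compute_dpc(raw)
  rmse <- sapply(c(1e-6, 1e-4, 1e-2, 1), function(b) {
    err <- reconstruct_phase(dpc, model, recon_config(beta = b))$phase - truth
    sqrt(mean((err - mean(err))^2))
  })
  expect_true(all(diff(rmse) > 0))
})

test_that("reconstruction of pure noise has near-zero background mean", {
  set.seed(11)
  dpc <- structure(list(dpc_x = matrix(rnorm(64^2, 0, 0.02), 64),
                        dpc_y = matrix(rnorm(64^2, 0, 0.02), 64),
                        pixel_size = 1), class = "dpc_pair")
  rec <- reconstruct_phase(dpc, model, recon_config())
  b <- rec$phase[c(1:8, 57:64), ]
  expect_lt(abs(median(b)), 0.02)
})

test_that("degenerate inputs are rejected or flagged", {
  expect_error(recon_config(beta = 0), "positive")
  expect_error(build_transfer_function(model, c(32, 32), 0), "positive")
  frames <- array(1, c(16, 16, 4))
  frames[1, 1, 1] <- -1
  expect_error(raw_frameset(frames, 1), "positive")
})
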