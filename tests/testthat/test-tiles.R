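test_that("tiling yields full tiles only, with unit-consistent counts", {
  img <- matrix(0, 720, 720)
  tl <- tile_image(img, pixel_size = 1, tile_size_um = 50)
  expect_equal(length(tl$tiles), 14 * 14)
  expect_equal(tl$tile_px, 50)
  # same physical grid at half the pixel pitch
  img2 <- matrix(0, 1440, 1440)
  tl2 <- tile_image(img2, pixel_size = 0.5, tile_size_um = 50)
  expect_equal(length(tl2$tiles), 196)
  expect_equal(tl2$tile_px, 100)
  # one tile when tile size equals image size
  tl3 <- tile_image(matrix(0, 64, 64), 1, tile_size_um = 64)
  expect_equal(length(tl3$tiles), 1)
  expect_error(tile_image(matrix(0, 64, 64), 1, tile_size_um = 5), "10 px")
})

test_that("GLCM features behave on constant and checkerboard tiles", {
  const <- texture_features(matrix(3.7, 20, 20))
  expect_equal(const[["glcm_energy"]], 1)
  expect_equal(const[["glcm_contrast"]], 0)
  expect_equal(const[["glcm_entropy"]], 0)
  # 2-level checkerboard with single horizontal offset: contrast = (dL)^2 = 1
  cb <- (outer(1:20, 1:20, "+") %% 2)
  tf <- texture_features(cb, tile_config(glcm_levels = 2,
                                         glcm_offsets = list(c(0, 1))))
  expect_equal(tf[["glcm_contrast"]], 1)
  # co-occurrence normalization: homogeneity and energy bounded
  set.seed(3)
  t1 <- matrix(rnorm(400), 20)
  tf2 <- texture_features(t1)
  expect_true(tf2[["glcm_energy"]] > 0 && tf2[["glcm_energy"]] <= 1)
})

test_that("fractal features recover fixture dimensions and pattern scores", {
  # bright/dark fixtures are bimodal: the Otsu binarization option applies
  ocfg <- tile_config(binarize = "otsu")
  sq_img <- matrix(0, 162, 162)
  sq_img[41:121, 41:121] <- make_fractal_fixture("filled_square", 81)
  sq <- fractal_features(sq_img + matrix(rnorm(162^2, 0, 0.05), 162), 1, ocfg)
  expect_equal(sq[["fractal_boxdim_global"]], 2, tolerance = 0.05)
  carpet <- make_fractal_fixture("sierpinski_carpet", 243)
  cf <- fractal_features(carpet + matrix(rnorm(243^2, 0, 0.05), 243), 1, ocfg)
  expect_equal(cf[["fractal_boxdim_global"]], log(8) / log(3), tolerance = 0.06)
  # empty tile flagged with zero features
  ef <- fractal_features(matrix(0, 30, 30), 1)
  expect_true(attr(ef, "empty"))
  expect_true(all(ef == 0))
})

test_that("aligned ellipses outscore equal-area disks on the curve pattern", {
  mk <- function(kind, seed) {
    set.seed(seed)
    m <- matrix(0, 50, 50)
    nobj <- if (kind == "ell") 12 else 6
    for (i in seq_len(nobj)) {
      cx <- runif(1, 6, 44); cy <- runif(1, 6, 44)
      obj <- if (kind == "ell")
        raster_ellipse(50, 4, 2, cx = cx, cy = cy, theta = 0.5)
      else raster_disk(50, 4, cx = cx, cy = cy)
      m[obj] <- 1
    }
    m
  }
  wins <- sapply(1:20, function(s) {
    fe <- fractal_features(mk("ell", s) + rnorm(2500, 0, 0.05), 1)
    fd <- fractal_features(mk("disk", s) + rnorm(2500, 0, 0.05), 1)
    c(fe[["curve_pattern_4_8um"]] > fd[["curve_pattern_4_8um"]],
      fd[["circle_pattern_34_38um2"]] > fe[["circle_pattern_34_38um2"]])
  })
  expect_gte(sum(wins[1, ]), 19)   # >= 95% of 20 seeds
  expect_gte(sum(wins[2, ]), 19)
})

test_that("Fourier features satisfy Parseval and resolve stripe patterns", {
  set.seed(5)
  tile <- matrix(rnorm(50 * 50), 50)
  ff <- fourier_features(tile, 1)
  wt <- (tile - mean(tile)) * organoidqpi:::hann2d(50)
  expect_equal(sum(ff[1:5]), mean(wt^2), tolerance = 1e-6)
  # vertical stripes of 10 um period
  X <- matrix(rep(1:100, each = 100), 100)
  fs <- fourier_features(sin(2 * pi * X / 10), 1)
  expect_equal(fs[["fourier_peak_freq"]], 0.1, tolerance = 0.01)
  expect_lt(min(abs(fs[["fourier_peak_orientation"]] - c(0, 180))), 5)
  expect_gt(fs[["fourier_anisotropy"]], 0.9)
})

test_that("white-noise tiles are nearly isotropic on average", {
  set.seed(9)
  fa <- aa <- numeric(20)
  for (i in 1:20) {
    tile <- matrix(rnorm(40 * 40), 40)
    fa[i] <- fourier_features(tile, 1)[["fourier_anisotropy"]]
    aa[i] <- autocorr_features(tile, 1)[["autocorr_anisotropy"]]
  }
  expect_lte(mean(fa), 0.1)
  expect_lte(mean(aa), 0.1)
})

test_that("autocorrelation length matches the Gaussian closed form", {
  # autocorrelation of a Gaussian of width sigma has 1/e radius 2*sigma
  g <- 5
  X <- matrix(rep(1:128, each = 128), 128); Y <- t(X)
  blob <- exp(-((X - 64)^2 + (Y - 64)^2) / (2 * g^2))
  ac <- autocorr_features(blob, 1)
  expect_equal(ac[["autocorr_length_um"]], 2 * g, tolerance = 0.15)
  expect_lt(ac[["autocorr_anisotropy"]], 0.1)
  # constant tile is flagged
  expect_true(attr(autocorr_features(matrix(1, 20, 20), 1), "empty"))
})

test_that("features are deterministic and finite on phantom tiles", {
  ph <- generate_organoid_phantom(small_phantom_spec(seed = 21))
  raw <- suppressWarnings(simulate_qobm_acquisition(ph, acquisition_spec(snr_db = 20),
                                                    seed = 3))
  rec <- reconstruct_phase(compute_dpc(raw), phase_transfer_model(), recon_config())
  tl <- tile_image(rec$phase, 1, tile_size_um = 48)
  cfg <- tile_config()
  v1 <- organoidqpi:::tile_feature_vector(tl$tiles[[5]], 1, cfg)
  v2 <- organoidqpi:::tile_feature_vector(tl$tiles[[5]], 1, cfg)
  expect_identical(v1, v2)
  for (k in c(1, 5, 9)) {
    v <- organoidqpi:::tile_feature_vector(tl$tiles[[k]], 1, cfg)
    expect_true(all(is.finite(v)))
  }
})

test_that("rotation-invariant features survive a 90-degree rotation", {
  set.seed(13)
  base <- matrix(0, 48, 48)
  for (i in 1:8) base[raster_ellipse(48, 5, 2, cx = runif(1, 8, 40),
                                     cy = runif(1, 8, 40), theta = 1)] <- 1
  tile <- base + rnorm(48^2, 0, 0.05)
  rot <- t(tile)[, 48:1]
  f1 <- fractal_features(tile, 1); f2 <- fractal_features(rot, 1)
  expect_equal(f2[["fractal_boxdim_global"]], f1[["fractal_boxdim_global"]],
               tolerance = 0.02)
  expect_equal(f2[["circle_pattern_34_38um2"]], f1[["circle_pattern_34_38um2"]],
               tolerance = 0.02)
  a1 <- autocorr_features(tile, 1); a2 <- autocorr_features(rot, 1)
  expect_equal(a2[["autocorr_length_um"]], a1[["autocorr_length_um"]],
               tolerance = 0.02)
})

test_that("the feature table has the contracted shape and determinism", {
  ph <- generate_organoid_phantom(small_phantom_spec(seed = 30))
  img <- ph$ri_map
  md <- data.frame(organoid = "A", group = "control", week = 1)
  ft <- extract_feature_table(list(img, img), rbind(md, md), pixel_size = 1,
                              config = tile_config(families = c("glcm", "fractal"),
                                                   tile_size_um = 48))
  ntiles <- length(tile_image(img, 1, 48)$tiles)
  expect_equal(nrow(ft), 2 * ntiles)
  expect_s3_class(ft, "feature_table")
  b1 <- ft[ft$image == 1, feature_names(ft)]
  b2 <- ft[ft$image == 2, feature_names(ft)]
  rownames(b1) <- rownames(b2) <- NULL
  expect_identical(b1, b2)
  expect_error(extract_feature_table(list(img), md, pixel_size = c(1, 2)),
               "mixed")
})
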