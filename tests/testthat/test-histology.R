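test_that("optical density conversion and its inverse are exact", {
  img <- array(1, c(4, 4, 3))
  expect_equal(rgb_to_od(img)[1, 1, ], c(0, 0, 0), ignore_attr = TRUE)
  img[1, 1, 2] <- 0.1
  od <- rgb_to_od(img)
  expect_equal(od[1, 1, 2], 1)
  # round trip
  set.seed(1)
  od2 <- array(runif(4 * 4 * 3, 0, 2), c(4, 4, 3))
  expect_equal(rgb_to_od(od_to_rgb(od2)), od2, tolerance = 1e-9,
               ignore_attr = TRUE)
  # zeros clipped with a warning
  img0 <- array(1, c(2, 2, 3)); img0[1, 1, 1] <- 0
  expect_warning(odc <- rgb_to_od(img0), "clipped")
  expect_equal(attr(odc, "clipped"), 1)
})

test_that("color deconvolution inverts pure and mixed stains", {
  M <- stain_matrix()
  expect_equal(colSums(unclass(M)^2), c(red = 1, blue = 1, residual = 1))
  # pure FastRed pixel of density d
  d <- 0.8
  od <- array(0, c(1, 1, 3))
  od[1, 1, ] <- M[, 1] * d
  dec <- color_deconvolve(od, M)
  expect_equal(dec$red[1, 1], d, tolerance = 1e-9)
  expect_lt(abs(dec$blue[1, 1]), 1e-9)
  # zero OD gives zero densities
  dec0 <- color_deconvolve(array(0, c(2, 2, 3)), M)
  expect_true(all(dec0$red == 0) && all(dec0$blue == 0))
  # random density fields round trip through mixing to 1e-6
  set.seed(9)
  a <- matrix(runif(64, 0, 1.5), 8); b <- matrix(runif(64, 0, 1.5), 8)
  od2 <- array(0, c(8, 8, 3))
  for (ch in 1:3) od2[, , ch] <- M[ch, 1] * a + M[ch, 2] * b
  dec2 <- color_deconvolve(od2, M)
  expect_equal(dec2$red, a, tolerance = 1e-6)
  expect_equal(dec2$blue, b, tolerance = 1e-6)
  expect_lt(max(abs(dec2$residual)), 1e-6)
})

test_that("synthetic histology round-trips known densities", {
  ph <- generate_organoid_phantom(small_phantom_spec(seed = 31))
  sim <- simulate_oro_histology(ph, d_red = 1.2, d_blue = 0.6)
  dec <- color_deconvolve(rgb_to_od(sim$rgb), stain_matrix())
  expect_equal(dec$red, sim$density_red, tolerance = 1e-6, ignore_attr = TRUE)
  expect_equal(dec$blue, sim$density_blue, tolerance = 1e-6, ignore_attr = TRUE)
  # phantom with no stained compartments gives pure white
  empty <- generate_organoid_phantom(small_phantom_spec(
    rosette_count = 0, fissure_count = 0, droplet_area_fraction = 0))
  sim0 <- simulate_oro_histology(empty, d_red = 1, d_blue = 0, d_tissue = 0)
  expect_true(all(sim0$rgb == 1))
  expect_error(simulate_oro_histology(ph, d_red = -1), "non-negative")
})

test_that("particle counting is exact on disjoint disks", {
  n <- 120
  dens <- matrix(0, n, n)
  centers <- cbind(c(20, 20, 60, 100, 100), c(20, 100, 60, 20, 100))
  for (i in 1:5) dens[raster_disk(n, 6, cx = centers[i, 1], cy = centers[i, 2])] <- 1
  tissue <- matrix(TRUE, n, n)
  st <- threshold_and_count(dens, tissue, threshold = 0.5, min_particle_px = 4)
  expect_equal(st$particle_count, 5)
  expect_equal(st$positive_pixels, sum(dens > 0.5))
  expect_equal(st$normalized_density, sum(dens > 0.5) / n^2)
  # blank map
  st0 <- threshold_and_count(matrix(0, n, n), tissue, threshold = 0.5)
  expect_equal(st0$particle_count, 0)
  expect_equal(st0$normalized_density, 0)
})

test_that("closing merges near-adjacent particles and small ones are removed", {
  m <- matrix(0, 40, 40)
  m[raster_disk(40, 4, cx = 12, cy = 20)] <- 1
  m[raster_disk(40, 4, cx = 22, cy = 20)] <- 1   # 1 px gap at x ~ 17
  tissue <- matrix(TRUE, 40, 40)
  st_plain <- threshold_and_count(m, tissue, threshold = 0.5)
  expect_equal(st_plain$particle_count, 2)
  st_closed <- threshold_and_count(m, tissue, threshold = 0.5, closing_px = 1)
  expect_equal(st_closed$particle_count, 1)
  # single-pixel speckle removed by the minimum particle size
  sp <- matrix(0, 20, 20); sp[5, 5] <- 1
  st_sp <- threshold_and_count(sp, matrix(TRUE, 20, 20), threshold = 0.5,
                               min_particle_px = 4)
  expect_equal(st_sp$particle_count, 0)
})

test_that("normalized density is monotone in threshold and padding-invariant", {
  set.seed(3)
  dens <- matrix(runif(400), 20)
  tissue <- matrix(TRUE, 20, 20)
  nd <- sapply(c(0.2, 0.5, 0.8), function(th)
    threshold_and_count(dens, tissue, threshold = th, min_particle_px = 1)$normalized_density)
  expect_true(all(diff(nd) <= 0))
  # padding the field with non-tissue must not change counts
  densp <- rbind(matrix(0, 5, 30), cbind(matrix(0, 20, 5), dens, matrix(0, 20, 5)),
                 matrix(0, 5, 30))
  tissuep <- rbind(matrix(FALSE, 5, 30),
                   cbind(matrix(FALSE, 20, 5), tissue, matrix(FALSE, 20, 5)),
                   matrix(FALSE, 5, 30))
  s1 <- threshold_and_count(dens, tissue, threshold = 0.5, min_particle_px = 1)
  s2 <- threshold_and_count(densp, tissuep, threshold = 0.5, min_particle_px = 1)
  expect_equal(s2$particle_count, s1$particle_count)
  expect_equal(s2$normalized_density, s1$normalized_density)
  expect_error(threshold_and_count(dens, tissue & FALSE), "empty")
})
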