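make_noise_map <- function(n = 32, voxel = 2, seed = 1) {
  set.seed(seed)
  volume3d(array(rnorm(n^3), rep(n, 3)), voxel)
}

test_that("FSC is 1 for identical and scaled maps, and symmetric", {
  a <- make_noise_map(seed = 1)
  fc <- fsc(a, a)
  expect_true(all(abs(fc$fsc - 1) < 1e-9))
  fc2 <- fsc(a, volume3d(3.7 * a$data, a$voxel))
  expect_true(all(abs(fc2$fsc - 1) < 1e-9))
  b <- make_noise_map(seed = 2)
  expect_equal(fsc(a, b)$fsc, fsc(b, a)$fsc, tolerance = 1e-12)
  expect_error(fsc(a, make_noise_map(n = 16)), "mismatch")
})

test_that("independent white-noise maps have near-zero shell correlation", {
  a <- make_noise_map(seed = 3)
  b <- make_noise_map(seed = 4)
  fc <- fsc(a, b)
  sel <- fc$n_voxels > 50
  expect_true(all(abs(fc$fsc[sel]) <= 3 / sqrt(fc$n_voxels[sel])))
})

test_that("resolution interpolates the threshold crossing in closed form", {
  ## construct a curve crossing 0.143 exactly halfway between the shells
  ## at 1/20 and 1/22 per Angstrom
  curve <- data.frame(freq = c(0.01, 1 / 22, 1 / 20, 0.06),
                      fsc = c(0.9, 0.143 + 0.05, 0.143 - 0.05, 0.02),
                      n_voxels = 100)
  class(curve) <- c("fsc_curve", "data.frame")
  attr(curve, "nyquist") <- 0.1
  r <- resolution_at(curve, 0.143)
  f_cross <- 1 / 22 + 0.5 * (1 / 20 - 1 / 22)
  expect_equal(as.numeric(r), 1 / f_cross, tolerance = 1e-12)
  expect_false(attr(r, "never_crossed"))
  ## identical maps: Nyquist with the never-crossed flag
  a <- make_noise_map()
  rn <- resolution_at(fsc(a, a), 0.143)
  expect_equal(as.numeric(rn), 2 * a$voxel)
  expect_true(attr(rn, "never_crossed"))
  ## 0.5 crossing is never at lower frequency than the 0.143 crossing
  mono <- data.frame(freq = seq(0.01, 0.1, length.out = 20),
                     fsc = seq(1, 0, length.out = 20), n_voxels = 100)
  class(mono) <- c("fsc_curve", "data.frame")
  attr(mono, "nyquist") <- 0.1
  expect_gte(as.numeric(resolution_at(mono, 0.143)),
             0)
  expect_gte(as.numeric(resolution_at(mono, 0.5)),
             as.numeric(resolution_at(mono, 0.143)))
})

test_that("low-pass filtering removes the stop band and keeps DC", {
  a <- make_noise_map(n = 32, voxel = 2, seed = 5)
  lp <- lowpass(a, 12)
  FF <- cryovertex:::cfft3(lp$data)
  kr <- cryovertex:::freq_radius3(32)
  kcut <- 32 * 2 / 12
  stop_power <- sum(Mod(FF[kr > kcut + 2])^2)
  tot_power <- sum(Mod(cryovertex:::cfft3(a$data)[kr > kcut + 2])^2)
  expect_lt(stop_power / tot_power, 0.01)
  expect_equal(mean(lp$data), mean(a$data), tolerance = 1e-9)
  ## the sharp filter (no transition band) is exactly idempotent
  lp1 <- lowpass(a, 12, edge_shells = 0)
  lp2 <- lowpass(lp1, 12, edge_shells = 0)
  expect_lt(max(abs(lp2$data - lp1$data)), 1e-6)
  expect_error(lowpass(a, 3), "Nyquist")
})

test_that("difference maps are zero on identity, linear and antisymmetric", {
  a <- make_noise_map(seed = 6)
  b <- make_noise_map(seed = 7)
  d0 <- difference_map(a, a, 12)
  expect_equal(max(abs(d0$data)), 0)
  ## linearity without intensity scaling, on pre-filtered inputs
  af <- lowpass(a, 12)
  bf <- lowpass(b, 12)
  dd <- difference_map(volume3d(af$data + bf$data, 2), af, 12,
                       scale = "none")
  expect_lt(max(abs(dd$data - lowpass(bf, 12)$data)),
            1e-6 * max(abs(bf$data)))
  dab <- difference_map(a, b, 12, scale = "none")
  dba <- difference_map(b, a, 12, scale = "none")
  expect_lt(max(abs(dab$data + dba$data)), 1e-9)
})

test_that("rotational correlation detects exact cyclic symmetry", {
  ## analytic C12 feature about the z axis
  n <- 48
  co <- cryovertex:::coord_arrays(n)
  rho <- sqrt(co$x^2 + co$y^2)
  phi <- atan2(co$y, co$x)
  v <- exp(-((rho - 8)^2 + (co$z - 10)^2) / 8) * (1 + 0.5 * cos(12 * phi))
  vol <- volume3d(v, 5)
  rc <- rotational_correlation(vol, axis = c(0, 0, 1), region = c(30, 90),
                               angle_step = 2, half_angle = 60)
  expect_equal(rc$corr[1], 1)
  expect_equal(attr(rc, "fold"), 12)
  expect_true(all(rc$corr[rc$angle %in% seq(30, 330, 30)] > 0.95))
  ## featureless region: flat curve, undetermined fold
  sph <- volume3d(array(cryovertex:::ball_profile(
    sqrt(co$x^2 + co$y^2 + co$z^2) * 5, 120, 20), rep(n, 3)), 5)
  rcs <- rotational_correlation(sph, axis = c(0, 0, 1), region = c(60, 110))
  expect_true(is.na(attr(rcs, "fold")))
})

test_that("6-fold features score higher at 6-fold than 12-fold-only angles", {
  spec <- fx_virion_spec()
  s <- spec$scale_factor
  rc <- rotational_correlation(fx_virion_phantom(),
                               region = spec$conduit_radial_extent * s,
                               angle_step = 2)
  a6 <- mean(rc$corr[rc$angle %in% seq(60, 300, 60)])
  a12 <- mean(rc$corr[rc$angle %in% seq(30, 330, 60)])
  expect_gt(a6, a12)
  expect_equal(attr(rc, "fold"), 6)
})

test_that("radial profiles are linear and flag shells correctly", {
  n <- 32
  co <- cryovertex:::coord_arrays(n)
  r <- sqrt(co$x^2 + co$y^2 + co$z^2)
  sph <- volume3d((r <= 10) * 1, 2)
  rp <- radial_profile(sph)
  expect_true(all(rp$intensity[rp$radius <= 16] >= 0))
  expect_equal(rp$intensity[rp$radius <= 14], rep(1, sum(rp$radius <= 14)),
               tolerance = 0.2)
  expect_lt(rp$intensity[rp$radius == 30], 0.05)
  rp2 <- radial_profile(volume3d(sph$data + 3, 2))
  expect_equal(rp2$intensity, rp$intensity + 3, tolerance = 1e-12)
})

test_that("FWHM thickness of a Gaussian peak is 2.3548 sigma", {
  r <- seq(0, 200, by = 2)
  sigma <- 12
  prof <- data.frame(radius = r, intensity = exp(-(r - 100)^2 / (2 * sigma^2)))
  class(prof) <- c("radial_profile", "data.frame")
  ext <- fwhm_extent(prof, c(50, 150))
  expect_lt(abs(ext[["thickness"]] - 2.3548 * sigma), 2)
  flat <- data.frame(radius = r, intensity = rep(1, length(r)))
  class(flat) <- c("radial_profile", "data.frame")
  expect_error(fwhm_extent(flat, c(50, 150)), "no peak")
})

test_that("relative membrane intensity reflects the construction", {
  spec <- phantom_spec()   # membrane amplitude scale 1
  s <- spec$scale_factor
  ph <- build_phantom(spec)
  ri <- relative_membrane_intensity(ph, spec$membrane_radii * s,
                                    spec$capsid_radii * s)
  expect_lt(abs(ri - 100), 2)
  ## no membrane at all
  ph0 <- build_phantom(phantom_spec(membrane_amplitude_scale = 1e-12))
  expect_lt(relative_membrane_intensity(ph0, spec$membrane_radii * s,
                                        spec$capsid_radii * s), 1)
  expect_error(relative_membrane_intensity(ph, c(100, 160), c(150, 200)),
               "disjoint")
})

test_that("segmented volumes and mass conversion follow the arithmetic", {
  n <- 32
  v <- array(0, rep(n, 3))
  v[1:10, 1:10, 1:10] <- 2
  vol <- volume3d(v, 5)                   # 10^3 voxels at 5 A
  expect_equal(segment_volume(vol, threshold = 1), 125)  # (10*0.5 nm)^3
  expect_equal(segment_volume(vol, threshold = 3), 0)
  expect_error(segment_volume(vol, region = array(FALSE, rep(n, 3)),
                              threshold = 1), "empty")
  expect_equal(round(volume_to_mass(83.6)), 69)
  expect_equal(volume_to_mass(1.212), 1)
  expect_equal(volume_to_mass(0), 0)
  expect_error(volume_to_mass(-1), "negative")
  ## exact linear round trip
  x <- c(10, 83.6, 250)
  expect_equal(mass_to_volume(volume_to_mass(x)), x, tolerance = 1e-12)
})
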