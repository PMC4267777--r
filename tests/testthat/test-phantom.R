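test_that("phantom specifications validate their invariants", {
  expect_error(phantom_spec(capsid_radii = c(322, 283)), "ordered")
  expect_error(phantom_spec(box_size = 32), "too small")
  expect_error(phantom_spec(channel_width = 200), "conduit diameter")
  expect_error(phantom_spec(portal_fold = 0), "folds")
  expect_error(phantom_spec(facet_modulation = 2), "\\[0, 1\\]")
  expect_error(phantom_spec(box_size = 33), "even")
})

test_that("zero-amplitude spec yields an all-zero volume", {
  spec <- phantom_spec(box_size = 48, voxel_size = 10, capsid_amplitude = 0,
                       portal_present = FALSE, conduit_present = FALSE)
  expect_equal(max(abs(build_phantom(spec)$data)), 0)
})

test_that("shell FWHM extents recover the specified radii within one voxel", {
  spec <- fx_virion_spec()  # capsid 283-322 A, membrane 223-260 A (Table 2)
  s <- spec$scale_factor
  vx <- spec$voxel_size
  rp <- radial_profile(fx_virion_phantom(), "central-section")
  cap <- fwhm_extent(rp, spec$capsid_radii * s + c(-3, 3) * vx)
  mem <- fwhm_extent(rp, spec$membrane_radii * s + c(-3, 3) * vx)
  expect_lt(abs(cap[["inner"]] - spec$capsid_radii[1] * s), vx)
  expect_lt(abs(cap[["outer"]] - spec$capsid_radii[2] * s), vx)
  expect_lt(abs(mem[["inner"]] - spec$membrane_radii[1] * s), vx)
  expect_lt(abs(mem[["outer"]] - spec$membrane_radii[2] * s), vx)
})

test_that("simulation is bit-reproducible for a fixed seed", {
  spec <- virion_spec(box_size = 48, voxel_size = 10)
  a <- simulate_stack(spec, 4, snr = 1, seed = 7)
  b <- simulate_stack(spec, 4, snr = 1, seed = 7)
  expect_identical(a$stack$images, b$stack$images)
  expect_identical(a$truth, b$truth)
  c <- simulate_stack(spec, 4, snr = 1, seed = 8)
  expect_false(identical(a$stack$images, c$stack$images))
})

test_that("simulated noise realizes the requested SNR", {
  spec <- virion_spec(box_size = 48, voxel_size = 10)
  n <- spec$box_size
  clean <- simulate_stack(spec, 60, snr = Inf, seed = 5)
  noisy <- simulate_stack(spec, 60, snr = 1, seed = 5)
  k <- seq_len(n) - 1 - n %/% 2
  supp <- outer(k, k, function(a, b) sqrt(a^2 + b^2)) * spec$voxel_size <=
    spec$capsid_radii[2] * spec$scale_factor
  ratios <- vapply(1:60, function(i) {
    sig <- clean$stack$images[, , i]
    nse <- noisy$stack$images[, , i] - sig
    var(sig[supp]) / var(as.numeric(nse))
  }, numeric(1))
  expect_lt(abs(mean(ratios) - 1), 0.05)
})

test_that("ground truth candidate indices reconstruct the true pose", {
  g <- icosahedral_group()
  sim <- simulate_stack(virion_spec(box_size = 48, voxel_size = 10), 5,
                        seed = 2)
  for (i in 1:5) {
    tr <- sim$truth[i, ]
    Ricos <- euler_to_matrix(tr$icos_phi, tr$icos_theta, tr$icos_psi)
    Rtrue <- euler_to_matrix(tr$phi, tr$theta, tr$psi)
    expect_lt(rotation_distance(Ricos %*% g$rotations[[tr$candidate_idx]],
                                Rtrue), 1e-5)
  }
})

test_that("the analytic symmetrized phantom is icosahedrally invariant", {
  g <- icosahedral_group()
  refsym <- fx_virion_sym()
  pj <- cryovertex:::fourier_projector(refsym)
  b <- cryovertex:::radial_bin_index(dim(refsym$data)[1])
  w <- function(img) cryovertex:::norm01(
    cryovertex:::subtract_radial_mean(
      cryovertex:::lowpass2d(img, refsym$voxel, 20), b))
  set.seed(1)
  R <- random_rotations(1)[[1]]
  p0 <- w(cryovertex:::project_fourier(pj, R))
  for (j in c(2, 17, 41)) {
    pg <- w(cryovertex:::project_fourier(pj, R %*% g$rotations[[j]]))
    expect_gt(sum(p0 * pg), 0.98)
  }
})

test_that("membrane disorder weakens the recovered membrane shell", {
  sV <- fx_virion_spec()
  sS <- sus_spec()
  s <- sV$scale_factor
  phV <- fx_virion_phantom()
  set.seed(3)
  phS <- build_phantom(sS, membrane_offset = rnorm(1, 0, sS$membrane_disorder_sigma))
  riV <- relative_membrane_intensity(phV, sV$membrane_radii * s,
                                     sV$capsid_radii * s)
  rp <- radial_profile(phS, "central-section")
  memw <- fwhm_extent(rp, sS$membrane_radii * s + c(-3, 3) * sS$voxel_size)[1:2]
  capw <- fwhm_extent(rp, sS$capsid_radii * s + c(-3, 3) * sS$voxel_size)[1:2]
  riS <- relative_membrane_intensity(phS, memw, capw)
  expect_gt(riV, 90)
  expect_lt(riS, 75)   # the Sus-like state's membrane is much weaker
})

test_that("the planted portal has exact 12-fold rotational symmetry", {
  spec <- fx_virion_spec()
  s <- spec$scale_factor
  rc <- rotational_correlation(fx_virion_phantom(),
                               region = spec$portal_radial_extent * s,
                               angle_step = 2)
  expect_equal(rc$corr[1], 1)
  at30 <- rc$corr[rc$angle %in% seq(30, 330, 30)]
  expect_true(all(at30 > 0.95))
  expect_equal(attr(rc, "fold"), 12)
})
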