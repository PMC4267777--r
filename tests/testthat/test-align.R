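test_that("identity-pose projection equals the straight z-sum", {
  set.seed(1)
  v <- volume3d(array(rnorm(32^3), rep(32, 3)), 2)
  p <- project(v, pose(0, 0, 0))
  expect_lt(max(abs(p - apply(v$data, c(1, 2), sum))), 1e-9)
})

test_that("projection is shift-equivariant", {
  set.seed(2)
  v <- volume3d(array(rnorm(32^3), rep(32, 3)), 2)
  p0 <- project(v, pose(20, 40, 10))
  ps <- project(v, pose(20, 40, 10, sx = 6, sy = -4))  # +3 / -2 px
  shifted <- matrix(0, 32, 32)
  shifted[4:32, 1:30] <- p0[1:29, 3:32]
  expect_gt(cor(as.numeric(ps[4:32, 1:30]),
                as.numeric(shifted[4:32, 1:30])), 1 - 1e-9)
  expect_error(project(v, pose(0, 0, 0, sx = 100)), "box/4")
})

test_that("the Fourier transform of a projection is the central section", {
  ## projection-slice theorem on a compact smooth object (its transform is
  ## smooth enough to interpolate)
  n <- 32
  co <- cryovertex:::coord_arrays(n)
  v <- exp(-((co$x - 3)^2 + (co$y + 2)^2 + (co$z - 4)^2) / (2 * 1.5^2)) +
    0.6 * exp(-((co$x + 5)^2 + (co$y - 1)^2 + (co$z + 2)^2) / (2 * 2^2))
  vol <- volume3d(v, 1)
  R <- euler_to_matrix(25, 63, 110)
  Fp <- cryovertex:::cfft2(project(vol, pose(25, 63, 110)))
  F3 <- cryovertex:::cfft3(v)
  A <- t(R)[, 1:2]
  k <- cryovertex:::freq_axis(n)
  pts <- cbind(as.numeric(outer(k, rep(1, n))),
               as.numeric(outer(rep(1, n), k)))
  q <- pts %*% t(A)
  sl <- complex(real = cryovertex:::cpp_interp3_cubic(Re(F3), q),
                imaginary = cryovertex:::cpp_interp3_cubic(Im(F3), q))
  sel <- sqrt(rowSums(pts^2)) < 10
  expect_gt(cor(c(Re(Fp)[sel], Im(Fp)[sel]), c(Re(sl)[sel], Im(sl)[sel])),
            0.99)
  ## the real-space and Fourier projection methods agree
  pf <- project(vol, pose(25, 63, 110), method = "fourier")
  pr <- project(vol, pose(25, 63, 110), method = "real")
  expect_gt(cor(as.numeric(pf), as.numeric(pr)), 0.99)
})

test_that("noiseless poses are recovered within a grid step (mod icos)", {
  g <- icosahedral_group()
  spec <- fx_tex_spec()
  refs <- fx_tex_refs()
  refsym <- build_phantom_symmetrized(spec)
  ph <- build_phantom(spec)
  set.seed(7)
  for (trial in 1:4) {
    R <- random_rotations(1)[[1]]
    sx <- runif(1, -15, 15); sy <- runif(1, -15, 15)
    img <- project(ph, cryovertex:::matrix_to_pose(R, sx, sy))
    res <- icos_align(img, refs = refs, refine = TRUE)
    expect_lt(rotation_distance_icos(res$rotation, R, g), 2)
    expect_lt(sqrt((res$pose$sx - sx)^2 + (res$pose$sy - sy)^2), 2)
  }
})

test_that("an image identical to a reference projection scores ~1", {
  refs <- fx_tex_refs()
  refsym <- build_phantom_symmetrized(fx_tex_spec())
  e <- refs$eulers[3, ]
  img <- project(refsym, pose(0, e[1], e[2]), method = "fourier")
  res <- icos_align(img, refs = refs, refine = FALSE)
  expect_gt(res$score, 0.98)
  expect_error(icos_align(matrix(0, refs$n, refs$n), refs = refs), "empty")
  expect_error(make_alignment_refs(refsym, freq_limit = 5), "Nyquist")
})

test_that("in-plane rotation of the image changes only the in-plane angle", {
  g <- icosahedral_group()
  refs <- fx_tex_refs()
  ph <- build_phantom(fx_tex_spec())
  set.seed(9)
  R <- random_rotations(1)[[1]]
  img <- project(ph, cryovertex:::matrix_to_pose(R, 0, 0))
  res0 <- icos_align(img, refs = refs, refine = TRUE)
  delta <- 24
  img_rot <- cryovertex:::cpp_resample_image(img, cryovertex:::rot2(-delta),
                                             0, 0)
  res1 <- icos_align(img_rot, refs = refs, refine = TRUE)
  ## rotating the image content by +delta left-composes Rz(delta)
  expect_lt(rotation_distance_icos(
    res1$rotation, cryovertex:::rot_z(delta) %*% res0$rotation, g), 1.5)
})

test_that("consistency filter keeps noiseless particles, rejects noise", {
  spec <- fx_tex_spec()
  refs <- fx_tex_refs()
  sim <- simulate_stack(spec, 6, snr = Inf, seed = 3)
  kept <- vapply(1:6, function(i) {
    consistency_filter(sim$stack$images[, , i], refs = refs,
                       perturbation_seed = 100 + i)$keep
  }, logical(1))
  expect_true(all(kept))   # >= 99% keep on noiseless stacks
  set.seed(42)
  kept_noise <- vapply(1:6, function(i) {
    consistency_filter(matrix(rnorm(48 * 48), 48, 48), refs = refs,
                       perturbation_seed = 200 + i)$keep
  }, logical(1))
  expect_lte(sum(kept_noise), 1)  # <= 5%-ish on pure noise
})

test_that("consistency criteria validate and reject borderline poses", {
  expect_error(consistency_criteria(angle_tol = 0), "tolerances")
  expect_error(consistency_criteria(n_repeats = 1), "n_repeats")
  cc <- consistency_criteria()
  expect_equal(cc$angle_tol, 0.5)
  expect_equal(cc$center_tol, 3)
})
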