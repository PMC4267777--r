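test_that("half-set splitting is deterministic by index parity", {
  sp <- split_halves(0:9)
  expect_equal(sp$even, c(0, 2, 4, 6, 8))
  expect_equal(sp$odd, c(1, 3, 5, 7, 9))
  sp3 <- split_halves(0:2)
  expect_equal(length(sp3$even), 2)
  expect_equal(length(sp3$odd), 1)
  expect_identical(split_halves(0:9), split_halves(0:9))
  expect_error(split_halves(1), "at least 2")
})

test_that("a point source reconstructs at its true location", {
  n <- 32
  v <- array(0, rep(n, 3))
  v[4 + n %/% 2 + 1, -3 + n %/% 2 + 1, 5 + n %/% 2 + 1] <- 1
  set.seed(3)
  rots <- random_rotations(200)
  imgs <- array(0, c(n, n, 200))
  for (i in 1:200) {
    imgs[, , i] <- cryovertex:::cpp_project(v, rots[[i]], c(0, 0, 0), n, 0, 0)
  }
  rec <- quiet_backproject(particle_stack(imgs, 1),
                           list(rotations = rots, sx = rep(0, 200),
                                sy = rep(0, 200)))
  mx <- arrayInd(which.max(rec$data), dim(rec$data)) - (n %/% 2 + 1)
  expect_equal(as.numeric(mx), c(4, -3, 5))
})

test_that("project-then-reconstruct preserves the volume to 0.9 Nyquist", {
  set.seed(3)
  n <- 32
  co <- cryovertex:::coord_arrays(n)
  v <- exp(-((co$x - 3)^2 + (co$y + 2)^2 + (co$z - 4)^2) / 8) +
    0.7 * exp(-((co$x + 5)^2 + (co$y - 1)^2 + (co$z + 2)^2) / 12.5) +
    cryovertex:::shell_profile(sqrt(co$x^2 + co$y^2 + co$z^2), 8, 12)
  vol <- volume3d(v, 1)
  m <- 300
  rots <- random_rotations(m)
  sx <- runif(m, -3, 3); sy <- runif(m, -3, 3)
  pj <- cryovertex:::fourier_projector(vol)
  imgs <- array(0, c(n, n, m))
  for (i in 1:m) {
    imgs[, , i] <- cryovertex:::project_fourier(pj, rots[[i]], sx[i], sy[i])
  }
  rec <- quiet_backproject(particle_stack(imgs, 1),
                           list(rotations = rots, sx = sx, sy = sy))
  fc <- fsc(rec, vol)
  sel <- fc$freq > 0 & fc$freq <= 0.9 * attr(fc, "nyquist")
  expect_true(all(fc$fsc[sel] >= 0.5))
})

test_that("icosahedral symmetrization equals the average of rotated copies", {
  set.seed(5)
  g <- icosahedral_group()
  v <- volume3d(array(rnorm(24^3), rep(24, 3)), 2)
  sym <- symmetrize_icos(v, g, interpolation = "linear")
  acc <- array(0, rep(24, 3))
  for (G in g$rotations) acc <- acc + cryovertex:::cpp_resample_vol(v$data, G)
  expect_lt(max(abs(sym$data - acc / 60)), 1e-6)
})

test_that("reconstruction is stable under particle permutation", {
  set.seed(6)
  n <- 24
  v <- array(rnorm(n^3), rep(n, 3))
  rots <- random_rotations(20)
  imgs <- array(0, c(n, n, 20))
  for (i in 1:20) {
    imgs[, , i] <- cryovertex:::cpp_project(v, rots[[i]], c(0, 0, 0), n, 0, 0)
  }
  rec1 <- quiet_backproject(particle_stack(imgs, 1),
                            list(rotations = rots, sx = rep(0, 20),
                                 sy = rep(0, 20)))
  perm <- sample(20)
  rec2 <- quiet_backproject(particle_stack(imgs[, , perm], 1),
                            list(rotations = rots[perm], sx = rep(0, 20),
                                 sy = rep(0, 20)))
  expect_lt(max(abs(rec1$data - rec2$data)), 1e-8 * max(abs(rec1$data)))
  expect_true(is.finite(sum(rec1$data^2)))
})

test_that("equal half-set seeds are rejected as cross-contamination", {
  st <- particle_stack(array(rnorm(16 * 16 * 4), c(16, 16, 4)), 2)
  expect_error(gold_standard_refine(st, seeds = c(5, 5)),
               "cross-contamination")
})

test_that("half maps of a pure-noise stack decorrelate beyond low frequencies", {
  set.seed(9)
  n <- 48
  st <- particle_stack(array(rnorm(n * n * 40), c(n, n, 40)), 5)
  gn <- suppressWarnings(
    gold_standard_refine(st, seeds = c(11, 22), n_iter = 1,
                         angular_step = 12, freq_limit = 20,
                         init_radius = 90))
  fn <- fsc(gn$half_a, gn$half_b)
  hi <- fn$fsc[fn$freq > 5 / (n * 5)]
  expect_lt(max(abs(hi)), 0.3)
  expect_lt(abs(mean(hi)), 0.1)
})
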