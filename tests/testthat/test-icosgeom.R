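test_that("the icosahedral group satisfies the group axioms", {
  g <- icosahedral_group()
  expect_length(g$rotations, 60)
  keys <- vapply(g$rotations, cryovertex:::mat_key, "")
  expect_true(cryovertex:::mat_key(diag(3)) %in% keys)
  ## orthonormal, proper
  for (R in g$rotations[c(1, 7, 23, 60)]) {
    expect_equal(crossprod(R), diag(3), tolerance = 1e-12)
    expect_equal(det(R), 1, tolerance = 1e-12)
  }
  ## closure and inverses by brute force over all 3600 products
  closed <- TRUE
  for (a in g$rotations) {
    for (b in g$rotations) {
      if (!(cryovertex:::mat_key(a %*% b) %in% keys)) closed <- FALSE
    }
    if (!(cryovertex:::mat_key(t(a)) %in% keys)) closed <- FALSE
  }
  expect_true(closed)
})

test_that("rotations permute the 12 vertex axes; stabilizers have order 5", {
  g <- icosahedral_group()
  ax <- g$vertex_axes
  expect_equal(ncol(ax), 12)
  expect_equal(colSums(ax^2), rep(1, 12), tolerance = 1e-12)
  for (R in g$rotations) {
    for (j in c(1, 5, 12)) {
      d <- colSums((ax - as.vector(R %*% ax[, j]))^2)
      expect_lt(min(d), 1e-9)
    }
  }
  for (j in 1:12) {
    stab <- sum(vapply(g$rotations, function(R) {
      sum((R %*% ax[, j] - ax[, j])^2) < 1e-12
    }, logical(1)))
    expect_equal(stab, 5)
  }
  ## the orbit of any one axis covers all 12
  orbit <- unique(vapply(g$rotations, function(R) {
    cryovertex:::axis_index(ax, R %*% ax[, 1])
  }, integer(1)))
  expect_setequal(orbit, 1:12)
  ## axis 1 has the largest +z component
  expect_equal(which.max(ax[3, ]), 1L)
})

test_that("candidate orbit size is vertices times stabilizer order", {
  expect_identical(candidate_orbit_size(12, 5), 60)
  expect_identical(candidate_orbit_size(1, 1), 1)
  expect_error(candidate_orbit_size(0, 5), "positive")
  expect_error(candidate_orbit_size(12, -1), "positive")
  ## equals the deduplicated orbit of a generic pose under the group
  R <- euler_to_matrix(21.3, 67.8, 143.2)
  cand <- enumerate_candidates(R)
  keys <- vapply(cand$rotations, cryovertex:::mat_key, "")
  expect_equal(length(unique(keys)), candidate_orbit_size(12, 5))
})

test_that("capsid stoichiometry arithmetic matches the unique-vertex geometry", {
  cs <- capsid_counts(720, 60, 1, 5)
  expect_equal(cs$mcp_monomers, 705)   # 720 - 5x3
  expect_equal(cs$penton_monomers, 55) # 60 - 5
  expect_equal(cs$mcp_monomers, 3 * cs$mcp_trimers)
  cs0 <- capsid_counts(720, 60, 0, 0)
  expect_equal(cs0$mcp_monomers, 720)
  expect_equal(cs0$penton_monomers, 60)
  expect_equal(capsid_counts(720, 60, 12, 0)$penton_monomers, 0)
  expect_error(capsid_counts(720, 60, 13, 0), "exceed")
})

test_that("pseudo-T arithmetic gives the double jelly-roll MCP copy number", {
  expect_identical(mcp_copies_from_pseudo_t(25), 720L)
  expect_identical(mcp_copies_from_pseudo_t(1), 0L)
  expect_identical(mcp_copies_from_pseudo_t(3), 60L)  # (180 - 60) / 2
  expect_error(mcp_copies_from_pseudo_t(25.02), "non-integral")
})

test_that("complex mass sums copy numbers times subunit masses", {
  expect_equal(complex_mass(c(6, 6), c(4.7, 5.4)), 60.6)
  expect_error(complex_mass(c(6, 6), 4.7), "length")
  expect_error(complex_mass(c(-1, 6), c(4.7, 5.4)), "negative")
})

test_that("canonical pose reduction is idempotent and orbit-invariant", {
  g <- icosahedral_group()
  set.seed(11)
  for (k in 1:5) {
    R <- random_rotations(1)[[1]]
    cp <- canonical_icos_pose(R, g)
    ## idempotent
    expect_equal(canonical_icos_pose(cp$R, g)$R, cp$R, tolerance = 1e-9)
    ## every orbit member reduces to the same representative
    R2 <- R %*% g$rotations[[sample(60, 1)]]
    expect_equal(canonical_icos_pose(R2, g)$R, cp$R, tolerance = 1e-9)
    ## the candidate index reconstructs the input rotation
    expect_lt(rotation_distance(
      cp$R %*% g$rotations[[cp$candidate_index]], R), 1e-7)
  }
})
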