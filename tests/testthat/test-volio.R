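test_that("MRC maps round-trip bitwise with their voxel size", {
  set.seed(1)
  ## float32-exact values so the mode-2 round trip is bitwise
  v <- volume3d(array(as.numeric(sample(-2^20:2^20, 32^3, TRUE)),
                      rep(32, 3)), 5)
  f <- withr::local_tempfile(fileext = ".mrc")
  write_map(v, f)
  v2 <- read_map(f)
  expect_identical(v2$data, v$data)
  expect_equal(v2$voxel, 5.0)
  hdr <- attr(v2, "header")
  expect_equal(hdr$mode, 2)
  expect_equal(hdr$axis_order, 1:3)
})

test_that("permuted axis order is canonicalized on read", {
  set.seed(2)
  v <- volume3d(array(rnorm(16^3), rep(16, 3)), 3)
  f <- withr::local_tempfile(fileext = ".mrc")
  write_map(v, f, axis_order = c(3L, 1L, 2L))
  v2 <- read_map(f)
  expect_equal(v2$data, v$data, tolerance = 1e-6)
})

test_that("particle stacks round-trip through MRC mode 2", {
  set.seed(3)
  st <- particle_stack(array(rnorm(24 * 24 * 5), c(24, 24, 5)), 4.5)
  f <- withr::local_tempfile(fileext = ".mrcs")
  write_stack(st, f)
  st2 <- read_stack(f)
  expect_equal(st2$images, st$images, tolerance = 1e-6)
  expect_equal(st2$voxel, 4.5)
})

test_that("pose tables round-trip losslessly and validate columns", {
  df <- data.frame(id = 0:4, phi = c(10.123456789, 20, 30, 40, 50),
                   theta = runif(5, 0, 180), psi = runif(5, 0, 360),
                   sx = rnorm(5), sy = rnorm(5), score = runif(5),
                   kept = c(TRUE, TRUE, FALSE, TRUE, TRUE))
  f <- withr::local_tempfile(fileext = ".tsv")
  write_table(df, f, kind = "poses")
  df2 <- read_table(f, kind = "poses")
  expect_equal(df2$phi, signif(df$phi, 9))
  expect_equal(df2$kept, df$kept)
  ## missing required column is named in the error
  expect_error(read_table({
    f2 <- withr::local_tempfile(fileext = ".tsv")
    write_table(df[setdiff(names(df), "psi")], f2)
    f2
  }, kind = "poses"), "psi")
  expect_error(write_table(df[-2], f, kind = "poses"), "phi")
})

test_that("assignment accuracy matches a hand count on a 5-row fixture", {
  truth <- data.frame(id = 0:4, candidate_idx = c(3L, 7L, 1L, 60L, 12L))
  asg <- data.frame(id = c(4L, 2L, 0L, 1L, 3L),
                    candidate_idx = c(12L, 5L, 3L, 7L, 59L))
  ## ids 4, 0, 1 agree; 2 and 3 do not -> 3/5
  expect_equal(assignment_accuracy(asg, truth), 0.6)
  expect_error(assignment_accuracy(data.frame(id = 9, candidate_idx = 1),
                                   truth), "overlap")
})

test_that("volume3d validates its inputs", {
  expect_error(volume3d(array(0, c(8, 8, 9)), 1), "cubic")
  expect_error(volume3d(array(0, c(9, 9, 9)), 1), "even")
  expect_error(volume3d(array(0, c(8, 8, 8)), -1), "positive")
})
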