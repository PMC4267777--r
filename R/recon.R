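## Unsymmetrized (and optionally icosahedrally symmetrized) 3-D
## reconstruction by direct Fourier inversion, with gold-standard half-set
## handling.

#' Even/odd half-set split
#'
#' Deterministic split of particle ids by index parity, fixed at the start
#' of refinement so that the two halves never share information.
#'
#' @param ids integer particle ids.
#' @param rule split rule (only `"even-odd-index"`).
#' @return object of class `half_set_split` with `even`, `odd`, `rule`.
#' @export
split_halves <- function(ids, rule = "even-odd-index") {
  if (length(ids) < 2) stop("need at least 2 particles to split")
  rule <- match.arg(rule)
  structure(list(even = ids[ids %% 2 == 0], odd = ids[ids %% 2 == 1],
                 rule = rule), class = "half_set_split")
}

#' Icosahedral symmetrization
#'
#' Averages a map over the 60 rotations of the icosahedral group
#' (by definition: the plain average of the 60 rotated copies).
#'
#' @param volume a [volume3d()].
#' @param group an [icosahedral_group()].
#' @param interpolation `"cubic"` (default; much closer to exact
#'   invariance) or `"linear"`.
#' @return a [volume3d()].
#' @export
symmetrize_icos <- function(volume, group = icosahedral_group(),
                            interpolation = c("cubic", "linear")) {
  interpolation <- match.arg(interpolation)
  fun <- if (interpolation == "cubic") cpp_resample_vol_cubic else
    cpp_resample_vol
  acc <- array(0, dim(volume$data))
  for (g in group$rotations) {
    acc <- acc + fun(volume$data, g)
  }
  volume3d(acc / length(group$rotations), volume$voxel)
}

## normalize a pose argument to list(rotations, sx, sy)
as_pose_list <- function(poses, n) {
  if (is.data.frame(poses)) {
    if (nrow(poses) != n) stop("missing poses: need one per image")
    rots <- lapply(seq_len(n), function(i) {
      euler_to_matrix(poses$phi[i], poses$theta[i], poses$psi[i])
    })
    list(rotations = rots, sx = poses$sx, sy = poses$sy)
  } else {
    if (length(poses$rotations) != n) stop("missing poses: need one per image")
    poses
  }
}

#' Direct Fourier-inversion reconstruction
#'
#' Inserts each image's centred 2-D transform as a central slice of the 3-D
#' transform (trilinear interpolation-weight accumulation), normalizes by
#' the accumulated weights with a Wiener-style floor (1e-3 of the maximum
#' weight), and inverse-transforms. Image shifts are undone by Fourier
#' phase factors before insertion. `symmetry = "icosahedral"` averages the
#' result over the 60 group rotations. Fourier shells (up to Nyquist) in
#' which no weight was accumulated are reported in a warning and in the
#' `underdetermined_shells` attribute.
#'
#' @param stack a [particle_stack()].
#' @param poses a data.frame (columns phi, theta, psi, sx, sy; one row per
#'   image) or a list with `rotations` (3x3 matrices), `sx`, `sy`
#'   (Angstrom).
#' @param symmetry `"none"` or `"icosahedral"`.
#' @param weight_floor relative Wiener floor on accumulated weights.
#' @param pad Fourier oversampling factor for the insertion grid (2 is the
#'   field's standard; interpolation error of the trilinear insertion
#'   scales down accordingly).
#' @return a [volume3d()].
#' @export
backproject <- function(stack, poses, symmetry = c("none", "icosahedral"),
                        weight_floor = 1e-3, pad = 2) {
  symmetry <- match.arg(symmetry)
  n <- dim(stack$images)[1]
  m <- pad * n
  nimg <- dim(stack$images)[3]
  pl <- as_pose_list(poses, nimg)
  accRe <- array(0, c(m, m, m))
  accIm <- array(0, c(m, m, m))
  accW <- array(0, c(m, m, m))
  k <- freq_axis(n)
  kx <- matrix(k, n, n)
  ky <- t(kx)
  pimg <- matrix(0, m, m)
  pidx <- (m - n) / 2 + seq_len(n)
  for (i in seq_len(nimg)) {
    ## zero-pad the image so its transform samples frequency at 1/pad
    ## voxel-frequency spacing (finer relative to the insertion grid)
    pimg[pidx, pidx] <- stack$images[, , i]
    FF <- cfft2(pimg)
    ## undo the in-plane shift (pixels) with the conjugate phase
    sxp <- pl$sx[i] / stack$voxel
    syp <- pl$sy[i] / stack$voxel
    if (sxp != 0 || syp != 0) {
      kp <- freq_axis(m) / pad
      FF <- FF * exp(2i * pi * (outer(kp, rep(1, m)) * sxp +
                                  outer(rep(1, m), kp) * syp) / n)
    }
    A <- t(pl$rotations[[i]])[, 1:2, drop = FALSE]
    cpp_insert_slice(accRe, accIm, accW, Re(FF), Im(FF), A)
  }
  floor_w <- weight_floor * max(accW)
  Fv <- complex(real = accRe, imaginary = accIm) / pmax(accW, floor_w)
  dim(Fv) <- c(m, m, m)
  volp <- Re(cifft3(Fv))
  ## crop the padded real-space volume back to the target box
  out <- volume3d(volp[pidx, pidx, pidx] * pad, stack$voxel)

  kr <- round(freq_radius3(m)) / pad
  shell_w <- tapply(accW, round(kr), sum)
  shells <- as.integer(names(shell_w))
  empty <- shells[shells <= n / 2 - 1 & shell_w == 0]
  if (length(empty)) {
    warning("underdetermined Fourier shell(s): ",
            paste(empty, collapse = ", "))
  }
  attr(out, "underdetermined_shells") <- empty
  if (symmetry == "icosahedral") out <- symmetrize_icos(out)
  out
}

## seeded random spherical starting model: soft sphere + smooth random field
random_sphere_model <- function(n, voxel, radius, seed) {
  set.seed(seed)
  co <- coord_arrays(n)
  r <- sqrt(co$x^2 + co$y^2 + co$z^2) * voxel
  sph <- ball_profile(r, radius, 4 * voxel)
  noise <- array(stats::rnorm(n^3), c(n, n, n))
  kr <- freq_radius3(n)
  m <- raised_cos_mask(kr, n / 8, 2)
  noise <- Re(cifft3(cfft3(noise) * m))
  noise <- noise / stats::sd(noise)
  volume3d(sph + 0.2 * noise, voxel)
}

#' Gold-standard independent half-set refinement
#'
#' Each half data set is refined fully independently, starting from a
#' separately seeded random spherical model: per iteration, the current
#' half-reference is icosahedrally symmetrized, all of the half's particles
#' are aligned against it by exhaustive projection matching, and the half
#' is reconstructed without symmetry imposition. The two halves never share
#' reference information; using the same seed for both halves is a hard
#' error (cross-contamination). The returned half maps feed the unmasked
#' FSC; the combined map is their average (display/analysis only).
#'
#' @param stack a [particle_stack()].
#' @param split a [split_halves()] result.
#' @param seeds two distinct integer seeds, one per half.
#' @param n_iter alignment/reconstruction iterations per half.
#' @param angular_step alignment grid step, degrees.
#' @param freq_limit alignment band limit, Angstrom; a vector of length
#'   `n_iter` anneals the band limit over iterations (frequency marching:
#'   coarse features first, to keep the bootstrap from random models out
#'   of premature high-frequency traps).
#' @param init_radius radius of the initial soft sphere, Angstrom.
#' @return object of class `gold_standard_result`: `half_a`, `half_b`
#'   (unsymmetrized [volume3d()] half maps), `combined`, `poses` (list of
#'   per-half pose data.frames).
#' @export
gold_standard_refine <- function(stack, split = split_halves(stack$ids),
                                 seeds = c(101, 202), n_iter = 2,
                                 angular_step = 8,
                                 freq_limit = 3 * stack$voxel,
                                 init_radius = NULL) {
  if (length(seeds) != 2 || seeds[1] == seeds[2])
    stop("cross-contamination: the two half-set seeds must differ")
  n <- dim(stack$images)[1]
  if (is.null(init_radius)) init_radius <- 0.4 * n * stack$voxel
  halves <- list(a = split$even, b = split$odd)
  maps <- list()
  poses_out <- list()
  for (hi in 1:2) {
    h <- names(halves)[hi]
    sel <- match(halves[[h]], stack$ids)
    sub <- particle_stack(stack$images[, , sel, drop = FALSE], stack$voxel,
                          stack$ids[sel])
    ref <- random_sphere_model(n, stack$voxel, init_radius, seeds[hi])
    poses <- NULL
    fl <- rep_len(freq_limit, n_iter)
    for (it in seq_len(n_iter)) {
      refs <- make_alignment_refs(symmetrize_icos(ref), angular_step,
                                  fl[it])
      rows <- vector("list", length(sub$ids))
      for (i in seq_along(sub$ids)) {
        res <- icos_align(sub$images[, , i], refs = refs, refine = FALSE)
        rows[[i]] <- data.frame(
          id = sub$ids[i], phi = res$pose$phi, theta = res$pose$theta,
          psi = res$pose$psi, sx = res$pose$sx, sy = res$pose$sy,
          score = res$score, kept = TRUE
        )
      }
      poses <- do.call(rbind, rows)
      ref <- backproject(sub, poses, symmetry = "none")
    }
    maps[[h]] <- ref
    poses_out[[h]] <- poses
  }
  structure(list(
    half_a = maps$a, half_b = maps$b,
    combined = volume3d((maps$a$data + maps$b$data) / 2, stack$voxel),
    poses = poses_out, seeds = seeds
  ), class = "gold_standard_result")
}

#' @export
print.gold_standard_result <- function(x, ...) {
  n <- dim(x$half_a$data)[1]
  cat(sprintf("gold_standard_result: two independent %d^3 half maps (seeds %d/%d)\n",
              n, x$seeds[1], x$seeds[2]))
  invisible(x)
}
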