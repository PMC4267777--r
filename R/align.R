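## Central-slice projection, icosahedral orientation determination, and the
## consistency-based particle rejection filter.

#' Projection pose
#'
#' Three intrinsic ZYZ Euler angles (degrees; `phi` is the in-plane angle)
#' plus a 2-D origin shift in Angstrom applied in the image plane.
#'
#' @param phi,theta,psi Euler angles in degrees.
#' @param sx,sy origin shift in Angstrom.
#' @return object of class `pose`.
#' @export
pose <- function(phi = 0, theta = 0, psi = 0, sx = 0, sy = 0) {
  structure(list(phi = phi %% 360, theta = theta, psi = psi %% 360,
                 sx = sx, sy = sy), class = "pose")
}

#' @export
print.pose <- function(x, ...) {
  cat(sprintf("pose: phi %.2f, theta %.2f, psi %.2f deg; shift (%.2f, %.2f) A\n",
              x$phi, x$theta, x$psi, x$sx, x$sy))
  invisible(x)
}

pose_matrix <- function(p) euler_to_matrix(p$phi, p$theta, p$psi)

matrix_to_pose <- function(R, sx = 0, sy = 0) {
  e <- matrix_to_euler(R)
  pose(e[1], e[2], e[3], sx, sy)
}

#' Project a volume
#'
#' Central-slice projection: the volume is rotated by the pose rotation,
#' integrated along the viewing (z) axis, and shifted in the image plane.
#' Linear in the volume. `method = "real"` integrates in real space
#' (trilinear scattering; exact for axis-aligned poses);
#' `method = "fourier"` extracts the central section of the oversampled
#' 3-D transform (the projection-slice theorem; higher fidelity near
#' Nyquist, at the cost of one 3-D FFT per call).
#'
#' @param volume a [volume3d()].
#' @param p a [pose()].
#' @param method `"real"` or `"fourier"`.
#' @return an N x N numeric projection image (matrix) with attribute
#'   `voxel`.
#' @export
project <- function(volume, p, method = c("real", "fourier")) {
  method <- match.arg(method)
  if (!inherits(volume, "volume3d")) stop("volume must be a volume3d")
  n <- dim(volume$data)[1]
  if (max(abs(c(p$sx, p$sy))) > n * volume$voxel / 4)
    stop("|shift| exceeds box/4")
  img <- if (method == "real") {
    cpp_project(volume$data, pose_matrix(p), c(0, 0, 0), n,
                p$sx / volume$voxel, p$sy / volume$voxel)
  } else {
    project_fourier(fourier_projector(volume), pose_matrix(p),
                    p$sx / volume$voxel, p$sy / volume$voxel)
  }
  attr(img, "voxel") <- volume$voxel
  img
}

## 2-D raised-cosine low-pass at `resolution` (A); edge width 2 shells
lowpass2d <- function(img, voxel, resolution) {
  n <- nrow(img)
  if (is.infinite(resolution)) return(img)
  kcut <- n * voxel / resolution
  k <- freq_axis(n)
  kr <- sqrt(outer(k^2, k^2, "+"))
  m <- raised_cos_mask(kr, kcut, 2)
  Re(cifft2(cfft2(img) * m))
}

raised_cos_mask <- function(kr, kcut, edge) {
  if (edge <= 0) return((kr <= kcut) * 1)
  m <- 0.5 * (1 + cos(pi * (kr - kcut) / edge))
  m[kr <= kcut] <- 1
  m[kr >= kcut + edge] <- 0
  m
}

rot2 <- function(deg) {
  a <- deg2rad(deg)
  matrix(c(cos(a), sin(a), -sin(a), cos(a)), 2, 2)
}

## quasi-uniform directions on the sphere (Fibonacci lattice) restricted to
## the canonical icosahedral asymmetric unit
asym_unit_directions <- function(angular_step, group = icosahedral_group()) {
  ntot <- max(60, ceiling(41253 / angular_step^2))
  i <- seq_len(ntot) - 0.5
  z <- 1 - 2 * i / ntot
  phi <- i * pi * (3 - sqrt(5))
  s <- sqrt(pmax(0, 1 - z^2))
  D <- rbind(s * cos(phi), s * sin(phi), z)
  wref <- c(0.2672612, 0.5345225, 0.8017837)  # fixed generic direction
  sc <- vapply(group$rotations, function(g) as.numeric(wref %*% (t(g) %*% D)),
               numeric(ncol(D)))
  keep <- max.col(sc, ties.method = "first") == 1L  # element 1 is the identity
  D[, keep, drop = FALSE]
}

## pose with phi = 0 whose reference-frame viewing direction is `d`
direction_to_euler <- function(d) {
  theta <- rad2deg(acos(max(-1, min(1, d[3]))))
  psi <- rad2deg(atan2(d[2], -d[1])) %% 360
  c(theta = theta, psi = psi)
}

norm01 <- function(x) {
  x <- x - mean(x)
  n <- sqrt(sum(x^2))
  if (n > 0) x / n else x
}

## integer-radius bin index for every pixel of an N x N image
radial_bin_index <- function(n) {
  k <- freq_axis(n)
  round(sqrt(outer(k^2, k^2, "+"))) + 1L
}

## subtract the circular (radial-bin) average about the image centre;
## removes the rotationally degenerate component of a centred particle
subtract_radial_mean <- function(img, bins) {
  m <- as.numeric(tapply(img, bins, mean))
  img - array(m[as.integer(bins)], dim(img))
}

## the circularly averaged image
radialize_image <- function(img, bins) {
  m <- as.numeric(tapply(img, bins, mean))
  array(m[as.integer(bins)], dim(img))
}

## bilinear sample of an image on a polar grid about the centre:
## returns an n_theta x n_radius matrix (rings in columns)
polar_sample <- function(img, radii, n_theta) {
  n <- nrow(img)
  c1 <- n %/% 2 + 1                       # 1-based centre index
  th <- (seq_len(n_theta) - 1) * 2 * pi / n_theta
  x <- c1 + outer(cos(th), radii)
  y <- c1 + outer(sin(th), radii)
  xi <- floor(x); yi <- floor(y)
  fx <- x - xi; fy <- y - yi
  g <- function(ix, iy) img[cbind(as.integer(ix), as.integer(iy))]
  v <- g(xi, yi) * (1 - fx) * (1 - fy) + g(xi + 1, yi) * fx * (1 - fy) +
    g(xi, yi + 1) * (1 - fx) * fy + g(xi + 1, yi + 1) * fx * fy
  matrix(v, n_theta, length(radii))
}

## Fourier-oversample an image 2x (zero-padded spectrum): steep radial
## profiles sampled at half-pixel spacing keep bilinear polar sampling from
## leaking the radial gradient into a grid-locked angular pattern
oversample2 <- function(img) {
  n <- nrow(img)
  FF <- cfft2(img)
  pad <- matrix(0 + 0i, 2 * n, 2 * n)
  idx <- n / 2 + seq_len(n)
  pad[idx, idx] <- FF
  Re(cifft2(pad))
}

## whitened, area-weighted polar representation + its theta-FFT
polar_prep <- function(img, radii, n_theta) {
  P <- polar_sample(oversample2(img), 2 * radii, n_theta)
  P <- sweep(P, 2, colMeans(P))            # remove each ring's mean
  P <- sweep(P, 2, sqrt(radii), "*")       # area weighting
  list(F = stats::mvfft(P), norm = sqrt(sum(P^2)))
}

## in-plane cross-correlation of two polar representations over all theta
## shifts; returns the normalized correlation per shift index
polar_xcorr <- function(ref, img) {
  cc <- rowSums(Re(stats::mvfft(Conj(ref$F) * img$F, inverse = TRUE))) /
    nrow(ref$F)
  cc / (ref$norm * img$norm)
}

## Oversampled Fourier-slice projector for reference templates: the
## reference is zero-padded (2x), transformed once, and projections at
## arbitrary poses are central slices interpolated from the padded
## transform. Free of the rotation-dependent interpolation artifacts of
## real-space resampling, which matters when discriminating
## pseudo-symmetric views of a quasi-spherical particle.
fourier_projector <- function(volume, oversample = 2) {
  n <- dim(volume$data)[1]
  m <- oversample * n
  pad <- array(0, c(m, m, m))
  idx <- (m - n) / 2 + seq_len(n)
  pad[idx, idx, idx] <- volume$data
  FF <- cfft3(pad)
  k <- freq_axis(n)
  pts <- cbind(as.numeric(outer(k, rep(1, n))),
               as.numeric(outer(rep(1, n), k)))
  list(Fre = Re(FF), Fim = Im(FF), n = n, os = oversample, pts = pts,
       voxel = volume$voxel)
}

project_fourier <- function(pj, R, sx_px = 0, sy_px = 0) {
  A <- t(R)[, 1:2, drop = FALSE]
  q <- (pj$pts %*% t(A)) * pj$os
  FF <- matrix(complex(real = cpp_interp3_cubic(pj$Fre, q),
                       imaginary = cpp_interp3_cubic(pj$Fim, q)), pj$n, pj$n)
  if (sx_px != 0 || sy_px != 0) {
    FF <- FF * exp(-2i * pi * (pj$pts[, 1] * sx_px + pj$pts[, 2] * sy_px) /
                     pj$n)
  }
  Re(cifft2(FF))
}

#' Precompute reference projections for icosahedral alignment
#'
#' Projects an icosahedrally symmetric reference on a quasi-uniform
#' direction grid covering one icosahedral asymmetric unit, band-limited to
#' `freq_limit`, and resamples each projection on a polar grid about the
#' image centre. In polar coordinates an in-plane rotation is an exact
#' circular shift, so the in-plane search introduces no resampling bias,
#' and each ring's mean is subtracted: the circularly symmetric component
#' of a (nearly) spherical particle carries no orientation information and
#' would otherwise dominate the correlation. The circular average itself is
#' kept as the template for the shift search. The result can be passed to
#' [icos_align()] to amortize the cost over a stack.
#'
#' @param reference a [volume3d()] (icosahedrally symmetric).
#' @param angular_step grid spacing in degrees (direction grid; the
#'   in-plane angle is sampled at 2 degrees regardless and refined by
#'   parabolic interpolation).
#' @param freq_limit resolution band limit in Angstrom.
#' @return object of class `align_refs`.
#' @export
make_alignment_refs <- function(reference, angular_step = 4,
                                freq_limit = 3 * reference$voxel) {
  n <- dim(reference$data)[1]
  if (freq_limit < 2 * reference$voxel) stop("freq_limit is beyond Nyquist")
  D <- asym_unit_directions(angular_step)
  eulers <- t(apply(D, 2, direction_to_euler))
  bins <- radial_bin_index(n)
  radii <- seq(1, n / 2 - 2)
  n_theta <- 180L
  projector <- fourier_projector(reference)
  polar <- vector("list", ncol(D))
  msum <- matrix(0, n, n)
  for (i in seq_len(ncol(D))) {
    R <- euler_to_matrix(0, eulers[i, 1], eulers[i, 2])
    p <- lowpass2d(project_fourier(projector, R), reference$voxel, freq_limit)
    msum <- msum + p
    polar[[i]] <- polar_prep(p, radii, n_theta)
  }
  shift_template <- norm01(radialize_image(msum / ncol(D), bins))
  structure(list(directions = D, eulers = eulers, polar = polar,
                 radii = radii, n_theta = n_theta,
                 shift_fft = Conj(cfft2(matrix(shift_template, n, n))),
                 bins = bins, projector = projector,
                 angular_step = angular_step, freq_limit = freq_limit,
                 voxel = reference$voxel, n = n, reference = reference),
            class = "align_refs")
}

## windowed cross-correlation peak: returns list(score, sx, sy) in pixels
## cc convention: cc(t) = sum_x ref(x) img(x - t), t centred
cc_peak <- function(Fref_conj, Fimg, shift_range, n) {
  cc <- Re(cifft2(Fref_conj * Fimg))
  c0 <- n %/% 2 + 1
  w <- -shift_range:shift_range
  win <- cc[c0 + w, c0 + w, drop = FALSE]
  i <- arrayInd(which.max(win), dim(win))
  sx <- w[i[1]]; sy <- w[i[2]]
  sc <- win[i[1], i[2]]
  ## parabolic subpixel refinement along each axis
  dx <- dy <- 0
  if (i[1] > 1 && i[1] < length(w)) {
    a <- win[i[1] - 1, i[2]]; b <- sc; cc2 <- win[i[1] + 1, i[2]]
    den <- a - 2 * b + cc2
    if (den < 0) dx <- 0.5 * (a - cc2) / den
  }
  if (i[2] > 1 && i[2] < length(w)) {
    a <- win[i[1], i[2] - 1]; b <- sc; cc2 <- win[i[1], i[2] + 1]
    den <- a - 2 * b + cc2
    if (den < 0) dy <- 0.5 * (a - cc2) / den
  }
  list(score = sc, sx = sx + dx, sy = sy + dy)
}

## best in-plane correlation of the image's polar representation against a
## template projection at viewing direction (theta, psi): parabolic
## interpolation of the circular cross-correlation peak
score_direction <- function(img_polar, refs, theta, psi) {
  R <- euler_to_matrix(0, theta, psi)
  p <- lowpass2d(project_fourier(refs$projector, R), refs$voxel,
                 refs$freq_limit)
  tmpl <- polar_prep(p, refs$radii, refs$n_theta)
  cc <- polar_xcorr(tmpl, img_polar)
  peak_circular(cc, 360 / refs$n_theta)
}

## argmax of a circular correlation curve with parabolic refinement;
## returns list(score, angle_deg)
peak_circular <- function(cc, step_deg) {
  p <- circular_maxima(cc, step_deg)
  list(score = p$score[1], angle = p$angle[1])
}

## all local maxima of a circular correlation curve (parabolic-refined),
## sorted by decreasing score
circular_maxima <- function(cc, step_deg) {
  nt <- length(cc)
  prev <- cc[c(nt, seq_len(nt - 1))]
  nxt <- cc[c(seq_len(nt)[-1], 1)]
  idx <- which(cc >= prev & cc > nxt)
  if (!length(idx)) idx <- which.max(cc)
  sc <- ang <- numeric(length(idx))
  for (j in seq_along(idx)) {
    i <- idx[j]
    a <- cc[if (i == 1) nt else i - 1]
    b <- cc[i]
    d <- cc[if (i == nt) 1 else i + 1]
    den <- a - 2 * b + d
    off <- if (den < 0) 0.5 * (a - d) / den else 0
    sc[j] <- b - 0.25 * (a - d) * off
    ang[j] <- ((i - 1 + off) * step_deg) %% 360
  }
  o <- order(-sc)
  list(score = sc[o], angle = ang[o])
}

## smallest circular angle difference in degrees
circ_diff <- function(a, b) {
  d <- abs(a - b) %% 360
  pmin(d, 360 - d)
}

## like score_direction, but scores the in-plane peak nearest `phi0`
## instead of the global one (tracks one in-plane basin during refinement)
score_direction_near <- function(img_polar, refs, theta, psi, phi0) {
  R <- euler_to_matrix(0, theta, psi)
  p <- lowpass2d(project_fourier(refs$projector, R), refs$voxel,
                 refs$freq_limit)
  tmpl <- polar_prep(p, refs$radii, refs$n_theta)
  pks <- circular_maxima(polar_xcorr(tmpl, img_polar), 360 / refs$n_theta)
  j <- which.min(circ_diff(pks$angle, phi0))
  list(score = pks$score[j], angle = pks$angle[j])
}

#' Icosahedral orientation determination by exhaustive projection matching
#'
#' Two-stage deterministic search. The particle centre is first located by
#' cross-correlating the image against the circularly averaged reference
#' template (FFT correlation over a windowed shift range with subpixel
#' parabolic refinement). The recentred image is then radially whitened
#' (circular average subtracted) and scored by normalized correlation
#' against every reference direction in the icosahedral asymmetric unit
#' and every in-plane angle on the grid, followed by a deterministic local
#' refinement of the three Euler angles (three halving levels down to
#' `angular_step / 27`). The returned pose is the canonical representative
#' within the asymmetric unit; grid ties break towards the lowest
#' (direction, in-plane) index.
#'
#' @param image N x N numeric matrix.
#' @param reference a [volume3d()] (icosahedrally symmetric), or `NULL` if
#'   `refs` is given.
#' @param angular_step grid step in degrees.
#' @param freq_limit band limit in Angstrom (default 3 x voxel size).
#' @param shift_range shift search window in pixels.
#' @param refine logical: run the local angular refinement.
#' @param refs precomputed [make_alignment_refs()] object.
#' @return list with `pose` (canonical [pose()], shifts in Angstrom),
#'   `score` (whitened NCC in `[-1, 1]`), and `rotation` (the canonical
#'   matrix).
#' @export
icos_align <- function(image, reference = NULL, angular_step = 4,
                       freq_limit = NULL, shift_range = 8, refine = TRUE,
                       refs = NULL) {
  if (is.null(refs)) {
    if (is.null(freq_limit)) freq_limit <- 3 * reference$voxel
    refs <- make_alignment_refs(reference, angular_step, freq_limit)
  }
  n <- refs$n
  if (all(image == 0)) stop("empty image")
  img_lp <- lowpass2d(image, refs$voxel, refs$freq_limit)

  ## stage 1: particle centre from the circularly averaged template
  pk <- cc_peak(refs$shift_fft, cfft2(norm01(img_lp)), shift_range, n)
  s_img <- c(pk$sx, pk$sy)

  ## stage 2: orientation of the recentred image in polar coordinates
  img_c <- cpp_resample_image(img_lp, diag(2), -s_img[1], -s_img[2])
  img_polar <- polar_prep(img_c, refs$radii, refs$n_theta)
  step_deg <- 360 / refs$n_theta
  grid <- lapply(seq_along(refs$polar), function(di) {
    pkc <- peak_circular(polar_xcorr(refs$polar[[di]], img_polar), step_deg)
    c(pkc$score, pkc$angle, refs$eulers[di, 1], refs$eulers[di, 2])
  })
  grid <- do.call(rbind, grid)
  ord <- order(-grid[, 1])
  sc <- grid[ord[1], 1]
  cur <- grid[ord[1], 2:4]

  if (refine) {
    ## near a pseudo-symmetric view the in-plane correlation has several
    ## close peaks: refine the viewing direction separately from every
    ## strong in-plane peak of the best grid directions, tracking that
    ## peak's basin, and keep the global best
    starts <- ord[seq_len(min(2, nrow(grid)))]
    sc <- -Inf
    for (si in starts) {
      di <- si
      cc <- polar_xcorr(refs$polar[[di]], img_polar)
      pks <- circular_maxima(cc, step_deg)
      npk <- min(4, length(pks$score))
      for (pi in seq_len(npk)) {
        cur_s <- c(pks$angle[pi], refs$eulers[di, 1], refs$eulers[di, 2])
        sc_s <- pks$score[pi]
        step <- refs$angular_step / 2
        for (lev in 1:4) {
          improved <- TRUE
          while (improved) {
            improved <- FALSE
            for (k in 2:3) for (d in c(-step, step)) {
              trial <- cur_s
              trial[k] <- trial[k] + d
              pkc <- score_direction_near(img_polar, refs, trial[2],
                                          trial[3], cur_s[1])
              if (pkc$score > sc_s + 1e-9) {
                sc_s <- pkc$score
                cur_s <- c(pkc$angle, trial[2], trial[3])
                improved <- TRUE
              }
            }
          }
          step <- step / 3
        }
        if (sc_s > sc) {
          sc <- sc_s
          cur <- cur_s
        }
      }
    }
  }
  R <- euler_to_matrix(cur[1], cur[2], cur[3])

  ## final shift polish against the full (unwhitened) template at the
  ## found orientation; the circular template of stage 1 ignores the
  ## particle's angular features
  tmpl <- lowpass2d(project_fourier(refs$projector, R), refs$voxel,
                    refs$freq_limit)
  pk2 <- cc_peak(Conj(cfft2(norm01(tmpl))), cfft2(norm01(img_lp)),
                 shift_range, n)
  s_img <- c(pk2$sx, pk2$sy)

  cp <- canonical_icos_pose(R)
  p <- matrix_to_pose(cp$R, s_img[1] * refs$voxel, s_img[2] * refs$voxel)
  list(pose = p, score = sc, rotation = cp$R)
}

#' Consistency criteria for particle selection
#'
#' Particles are kept only when repeated, independently perturbed
#' orientation searches agree to within `angle_tol` degrees (geodesic
#' rotation distance modulo the icosahedral group) and `center_tol`
#' Angstrom.
#'
#' @param angle_tol orientation tolerance, degrees (default 0.5).
#' @param center_tol centre tolerance, Angstrom (default 3).
#' @param n_repeats number of independent runs (default 2).
#' @return object of class `consistency_criteria`.
#' @export
consistency_criteria <- function(angle_tol = 0.5, center_tol = 3,
                                 n_repeats = 2) {
  if (angle_tol <= 0 || center_tol <= 0) stop("tolerances must be > 0")
  if (n_repeats < 2) stop("n_repeats must be >= 2")
  structure(list(angle_tol = angle_tol, center_tol = center_tol,
                 n_repeats = n_repeats), class = "consistency_criteria")
}

#' Consistency-based particle filter
#'
#' Runs [icos_align()] `n_repeats` times from independently perturbed
#' starting conditions (a random in-plane rotation and shift applied to the
#' image, undone after alignment). The particle is kept iff every pairwise
#' orientation difference (modulo the icosahedral group) is below
#' `angle_tol` and every pairwise centre difference is below `center_tol`.
#'
#' @param image N x N numeric matrix.
#' @param reference a [volume3d()], or `NULL` if `refs` given.
#' @param criteria a [consistency_criteria()].
#' @param perturbation_seed RNG seed for the perturbations.
#' @param refs optional precomputed [make_alignment_refs()].
#' @param ... passed to [icos_align()].
#' @return list with `keep` (logical), `pose` (accepted [pose()] from the
#'   first run), `max_angle_diff`, `max_center_diff`, and the per-run poses.
#' @export
consistency_filter <- function(image, reference = NULL,
                               criteria = consistency_criteria(),
                               perturbation_seed = 1, refs = NULL, ...) {
  if (is.null(refs)) refs <- make_alignment_refs(reference, ...)
  set.seed(perturbation_seed)
  vx <- refs$voxel
  rots <- list()
  shifts <- list()
  for (k in seq_len(criteria$n_repeats)) {
    delta <- stats::runif(1, 0, 360)
    tpx <- stats::runif(2, -2, 2) / vx
    pert <- cpp_resample_image(image, rot2(delta), tpx[1], tpx[2])
    res <- icos_align(pert, refs = refs)
    ## undo the perturbation: R = Rz(delta) R', s = Rz(delta) (s' - t)
    R <- rot_z(delta) %*% res$rotation
    s <- rot2(delta) %*% (c(res$pose$sx, res$pose$sy) / vx - tpx) * vx
    rots[[k]] <- R
    shifts[[k]] <- as.numeric(s)
  }
  max_ang <- 0
  max_cen <- 0
  for (a in seq_len(criteria$n_repeats - 1)) {
    for (b in (a + 1):criteria$n_repeats) {
      max_ang <- max(max_ang, rotation_distance_icos(rots[[a]], rots[[b]]))
      max_cen <- max(max_cen, sqrt(sum((shifts[[a]] - shifts[[b]])^2)))
    }
  }
  keep <- max_ang < criteria$angle_tol && max_cen < criteria$center_tol
  cp <- canonical_icos_pose(rots[[1]])
  list(keep = keep,
       pose = matrix_to_pose(cp$R, shifts[[1]][1], shifts[[1]][2]),
       max_angle_diff = max_ang, max_center_diff = max_cen,
       rotations = rots, shifts = shifts)
}
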