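## Map metrology: FSC and resolution criteria, matched-resolution
## difference maps, rotational-correlation symmetry detection, radial
## profiles / FWHM shell extents, relative membrane intensity, segmentation
## volume and density volume-to-mass conversion.

#' Fourier shell correlation (unmasked)
#'
#' Per-shell normalized cross-correlation of the Fourier coefficients of
#' two maps on the same grid, with integer-voxel shells. No masking is
#' applied to either input.
#'
#' @param mapA,mapB [volume3d()] maps on the same grid.
#' @return object of class `fsc_curve`: data.frame with `freq` (spatial
#'   frequency, 1/Angstrom), `fsc`, `n_voxels` (voxels per shell), plus
#'   attributes `voxel` and `nyquist`.
#' @export
fsc <- function(mapA, mapB) {
  stopifnot_same_grid(mapA, mapB)
  n <- dim(mapA$data)[1]
  FA <- cfft3(mapA$data)
  FB <- cfft3(mapB$data)
  kr <- round(freq_radius3(n))
  shells <- 0:(n %/% 2)
  kr[kr > n %/% 2] <- -1L
  num <- tapply(Re(FA * Conj(FB)), kr, sum)
  pa <- tapply(abs(FA)^2, kr, sum)
  pb <- tapply(abs(FB)^2, kr, sum)
  cnt <- tapply(rep(1, length(kr)), kr, sum)
  keep <- names(num) %in% as.character(shells)
  num <- num[keep]; pa <- pa[keep]; pb <- pb[keep]; cnt <- cnt[keep]
  val <- num / sqrt(pa * pb)
  val[!is.finite(val)] <- 0
  k <- as.integer(names(num))
  out <- data.frame(freq = k / (n * mapA$voxel), fsc = as.numeric(val),
                    n_voxels = as.integer(cnt))
  out <- out[order(out$freq), ]
  rownames(out) <- NULL
  class(out) <- c("fsc_curve", "data.frame")
  attr(out, "voxel") <- mapA$voxel
  attr(out, "nyquist") <- 1 / (2 * mapA$voxel)
  out
}

#' Resolution at an FSC threshold
#'
#' Finds the first downward crossing of the threshold, linearly
#' interpolated in frequency between shells. If the curve never crosses,
#' the Nyquist resolution is returned with attribute `never_crossed`.
#'
#' @param curve an [fsc()] curve.
#' @param threshold FSC criterion (0.143 for half-map gold-standard
#'   resolution, 0.5 for map-vs-model).
#' @return resolution in Angstrom (attribute `never_crossed` logical).
#' @export
resolution_at <- function(curve, threshold = 0.143) {
  if (!nrow(curve)) stop("empty FSC curve")
  f <- curve$freq
  v <- curve$fsc
  for (i in seq_len(nrow(curve) - 1)) {
    if (v[i] >= threshold && v[i + 1] < threshold) {
      fc <- f[i] + (v[i] - threshold) / (v[i] - v[i + 1]) * (f[i + 1] - f[i])
      out <- 1 / fc
      attr(out, "never_crossed") <- FALSE
      return(out)
    }
  }
  out <- 1 / attr(curve, "nyquist")
  if (is.null(attr(curve, "nyquist"))) out <- 1 / max(f)
  attr(out, "never_crossed") <- TRUE
  out
}

#' @export
print.fsc_curve <- function(x, ...) {
  cat(sprintf("fsc_curve: %d shells to %.3f 1/A\n", nrow(x), max(x$freq)))
  r143 <- resolution_at(x, 0.143)
  r5 <- resolution_at(x, 0.5)
  cat(sprintf("  resolution: %.2f A (FSC 0.143%s), %.2f A (FSC 0.5%s)\n",
              r143, if (attr(r143, "never_crossed")) ", never crossed" else "",
              r5, if (attr(r5, "never_crossed")) ", never crossed" else ""))
  invisible(x)
}

#' @export
plot.fsc_curve <- function(x, ...) {
  graphics::plot(x$freq, x$fsc, type = "l", xlab = "spatial frequency (1/A)",
                 ylab = "FSC", ylim = c(min(0, min(x$fsc)), 1), ...)
  graphics::abline(h = c(0.143, 0.5), lty = 3)
  invisible(x)
}

#' Low-pass filter a map
#'
#' Fourier filter with a raised-cosine edge (width `edge_shells` shells)
#' centred past the cutoff frequency `1/resolution`; the passband (and the
#' DC component) is preserved exactly and the stopband is zeroed exactly.
#' With `edge_shells = 0` the filter is a sharp shell mask and exactly
#' idempotent; the default soft edge re-attenuates its own 2-shell
#' transition band on repeated application (everywhere else idempotent).
#'
#' @param volume a [volume3d()].
#' @param resolution target resolution in Angstrom (>= 2 x voxel size).
#' @param edge_shells width of the raised-cosine edge in shells.
#' @return a [volume3d()].
#' @export
lowpass <- function(volume, resolution, edge_shells = 2) {
  n <- dim(volume$data)[1]
  if (resolution < 2 * volume$voxel)
    stop("resolution is beyond Nyquist (2 x voxel size)")
  kcut <- n * volume$voxel / resolution
  m <- raised_cos_mask(freq_radius3(n), kcut, edge_shells)
  volume3d(Re(cifft3(cfft3(volume$data) * m)), volume$voxel)
}

#' Matched-resolution difference map
#'
#' Both maps are low-pass filtered to the common resolution (the higher
#' resolution map is thereby filtered to the lower one), optionally
#' intensity-scaled so that their mean absolute density over the capsid
#' shell agrees (subtraction across datasets is meaningless at arbitrary
#' intensity scales), then subtracted voxelwise (A - B).
#'
#' @param mapA,mapB [volume3d()] maps on the same grid.
#' @param common_resolution filter resolution in Angstrom.
#' @param scale `"capsid"` (scale B to A over `capsid_window`) or
#'   `"none"`.
#' @param capsid_window radial window (inner, outer; Angstrom) of the
#'   capsid shell used for intensity scaling.
#' @return a [volume3d()] difference map.
#' @export
difference_map <- function(mapA, mapB, common_resolution,
                           scale = c("capsid", "none"),
                           capsid_window = NULL) {
  scale <- match.arg(scale)
  stopifnot_same_grid(mapA, mapB)
  a <- lowpass(mapA, common_resolution)
  b <- lowpass(mapB, common_resolution)
  if (scale == "capsid") {
    n <- dim(a$data)[1]
    co <- coord_arrays(n)
    r <- sqrt(co$x^2 + co$y^2 + co$z^2) * a$voxel
    if (is.null(capsid_window)) {
      ## default: the shell around the radius of maximal average density
      rp <- radial_profile(a)
      pk <- rp$radius[which.max(rp$intensity)]
      capsid_window <- c(pk - 5 * a$voxel, pk + 5 * a$voxel)
    }
    sel <- r >= capsid_window[1] & r <= capsid_window[2]
    ma <- mean(abs(a$data[sel]))
    mb <- mean(abs(b$data[sel]))
    if (mb > 0) b$data <- b$data * (ma / mb)
  }
  volume3d(a$data - b$data, a$voxel)
}

#' Rotational correlation about an axis
#'
#' Resamples the map on a cylindrical grid about `axis` restricted to the
#' annular region (`rmin`-`rmax` in spherical radius, within a cone of
#' `half_angle` about the +axis side), then correlates the sampled field
#' with its own rotation at every multiple of `angle_step`. The dominant
#' fold is the n in 1..24 maximizing the mean correlation at the nontrivial
#' multiples of 360/n; a featureless (axially symmetric) region gives a
#' flat curve and an undetermined fold (`NA`).
#'
#' @param volume a [volume3d()].
#' @param axis unit 3-vector (default: vertex axis 1 of the icosahedral
#'   group).
#' @param region numeric (rmin, rmax) radial bounds in Angstrom.
#' @param angle_step sampling step in degrees (must divide 360).
#' @param half_angle cone half-angle about the axis, degrees.
#' @param flat_tol curve range below which the fold is undetermined.
#' @return object of class `rot_corr_curve`: data.frame `angle`, `corr`;
#'   attributes `fold` (dominant fold or NA), `fold_scores`, `axis`,
#'   `region`.
#' @export
rotational_correlation <- function(volume, axis = NULL, region,
                                   angle_step = 2, half_angle = 40,
                                   flat_tol = 1e-3) {
  if (is.null(axis)) axis <- icosahedral_group()$vertex_axes[, 1]
  if (360 %% angle_step != 0) stop("angle_step must divide 360")
  n <- dim(volume$data)[1]
  vx <- volume$voxel
  if (region[2] >= n * vx / 2) stop("region extends beyond the map")
  a <- axis / sqrt(sum(axis^2))
  fr <- axis_frame(a)
  ## cylindrical sample grid within the annular cone
  hs <- seq(region[1] * cos(deg2rad(half_angle)) * 0.9, region[2],
            by = vx / 2)
  rhos <- seq(vx / 2, region[2] * sin(deg2rad(half_angle)) * 1.1, by = vx / 2)
  thetas <- deg2rad(seq(0, 360 - angle_step, by = angle_step))
  g <- expand.grid(h = hs, rho = rhos)
  r <- sqrt(g$h^2 + g$rho^2)
  ang <- rad2deg(atan2(g$rho, g$h))
  keep <- r >= region[1] & r <= region[2] & ang <= half_angle
  if (!any(keep)) stop("empty rotational-correlation region")
  g <- g[keep, ]
  nt <- length(thetas)
  ## sample S[point, theta]
  S <- matrix(0, nrow(g), nt)
  for (t in seq_len(nt)) {
    dirv <- outer(cos(thetas[t]) * fr$u + sin(thetas[t]) * fr$v, g$rho)
    pts <- t(outer(a, g$h) + dirv) / vx
    S[, t] <- cpp_interp3(volume$data, pts)
  }
  v0 <- as.numeric(S)
  corr <- vapply(seq_len(nt) - 1L, function(shift) {
    vs <- as.numeric(S[, ((seq_len(nt) - 1L + shift) %% nt) + 1L])
    if (stats::sd(v0) == 0) return(1)
    stats::cor(v0, vs)
  }, numeric(1))
  angles <- rad2deg(thetas)
  fold_scores <- vapply(1:24, function(f) {
    mult <- (360 / f) * seq_len(f - 1)
    sel <- angles %in% round(mult %% 360, 9)
    if (!any(sel)) return(NA_real_)
    mean(corr[sel])
  }, numeric(1))
  ## dominant fold from the harmonic content of the correlation curve: a
  ## Cn feature makes the curve periodic with period 360/n, so its
  ## strongest harmonic sits at n. (A plain argmax over mean correlation
  ## at multiples would always report a divisor fold, since C2n contains
  ## Cn.)
  fold <- if (max(corr[-1]) - min(corr) < flat_tol) NA_integer_ else {
    amp <- Mod(stats::fft(corr - mean(corr)))[2:25]
    which.max(amp)
  }
  out <- data.frame(angle = angles, corr = corr)
  class(out) <- c("rot_corr_curve", "data.frame")
  attr(out, "fold") <- fold
  attr(out, "fold_scores") <- fold_scores
  attr(out, "axis") <- a
  attr(out, "region") <- region
  out
}

#' @export
print.rot_corr_curve <- function(x, ...) {
  f <- attr(x, "fold")
  cat(sprintf("rot_corr_curve: %d angles; dominant fold: %s\n", nrow(x),
              if (is.na(f)) "undetermined (featureless)" else f))
  invisible(x)
}

#' Radial density profile
#'
#' Mean intensity per 1-voxel radius bin, either over full 3-D shells or
#' over annuli of the central section (the z = centre slice), the
#' convention used for relative membrane intensity.
#'
#' @param volume a [volume3d()].
#' @param mode `"shell"` (3-D) or `"central-section"`.
#' @return object of class `radial_profile`: data.frame `radius`
#'   (Angstrom, bin centres) and `intensity`.
#' @export
radial_profile <- function(volume, mode = c("shell", "central-section")) {
  mode <- match.arg(mode)
  n <- dim(volume$data)[1]
  vx <- volume$voxel
  if (mode == "shell") {
    co <- coord_arrays(n)
    r <- round(sqrt(co$x^2 + co$y^2 + co$z^2))
    vals <- volume$data
  } else {
    k <- freq_axis(n)
    r <- round(sqrt(outer(k^2, k^2, "+")))
    vals <- volume$data[, , n %/% 2 + 1]
  }
  m <- tapply(vals, r, mean)
  rr <- as.integer(names(m))
  keep <- rr <= n %/% 2
  out <- data.frame(radius = rr[keep] * vx, intensity = as.numeric(m[keep]))
  out <- out[order(out$radius), ]
  rownames(out) <- NULL
  class(out) <- c("radial_profile", "data.frame")
  attr(out, "voxel") <- vx
  attr(out, "mode") <- mode
  out
}

#' FWHM extent of a radial peak
#'
#' Locates the single peak inside the window, subtracts the baseline (the
#' minimum within the window), and returns the radii at which the profile
#' crosses half the peak maximum on each side (linear interpolation), plus
#' the thickness (outer - inner).
#'
#' @param profile a [radial_profile()].
#' @param peak_window numeric (inner, outer) radius bounds in Angstrom.
#' @return named numeric `c(inner, outer, thickness)` in Angstrom.
#' @export
fwhm_extent <- function(profile, peak_window) {
  sel <- which(profile$radius >= peak_window[1] &
                 profile$radius <= peak_window[2])
  if (length(sel) < 3) stop("no peak in window")
  r <- profile$radius[sel]
  v <- profile$intensity[sel]
  ip <- which.max(v)
  if (ip == 1 || ip == length(v)) stop("no peak in window")
  base <- min(v)
  if (max(v) - base <= 0) stop("no peak in window")
  half <- base + (max(v) - base) / 2
  ## inner crossing
  i <- ip
  while (i > 1 && v[i - 1] > half) i <- i - 1
  if (i == 1) stop("no peak in window: inner flank does not fall to half maximum")
  inner <- r[i - 1] + (half - v[i - 1]) / (v[i] - v[i - 1]) * (r[i] - r[i - 1])
  ## outer crossing
  i <- ip
  while (i < length(v) && v[i + 1] > half) i <- i + 1
  if (i == length(v)) stop("no peak in window: outer flank does not fall to half maximum")
  outer_r <- r[i] + (v[i] - half) / (v[i] - v[i + 1]) * (r[i + 1] - r[i])
  c(inner = inner, outer = outer_r, thickness = outer_r - inner)
}

#' Relative membrane intensity
#'
#' Ratio (percent) of the mean central-section annular intensity in the
#' membrane radial window to that in the capsid window, the per-map proxy
#' for membrane order/rigidity.
#'
#' @param volume a [volume3d()].
#' @param membrane_window,capsid_window disjoint (inner, outer) radial
#'   windows in Angstrom.
#' @return percentage.
#' @export
relative_membrane_intensity <- function(volume, membrane_window,
                                        capsid_window) {
  if (membrane_window[2] > capsid_window[1] &&
      capsid_window[2] > membrane_window[1])
    stop("membrane and capsid windows must be disjoint")
  n <- dim(volume$data)[1]
  vx <- volume$voxel
  k <- freq_axis(n)
  r <- sqrt(outer(k^2, k^2, "+")) * vx
  sl <- volume$data[, , n %/% 2 + 1]
  mem <- mean(sl[r >= membrane_window[1] & r <= membrane_window[2]])
  cap <- mean(sl[r >= capsid_window[1] & r <= capsid_window[2]])
  if (cap == 0) stop("zero capsid intensity")
  100 * mem / cap
}

#' Segmented density volume
#'
#' Counts the voxels at or above the threshold within the region mask and
#' converts to nm^3. The threshold is a required explicit parameter: there
#' is no meaningful default contour level.
#'
#' @param volume a [volume3d()].
#' @param region logical array (same grid) or NULL for the whole map.
#' @param threshold density threshold.
#' @return volume in nm^3.
#' @export
segment_volume <- function(volume, region = NULL, threshold) {
  if (is.null(region)) region <- TRUE
  else if (!any(region)) stop("empty region")
  nvox <- sum(volume$data >= threshold & region)
  nvox * (volume$voxel / 10)^3
}

#' Density volume to molecular mass
#'
#' Converts a segmented density volume to molecular mass with the standard
#' protein volume-to-mass constant (default 1.212 nm^3/kDa, consistent
#' with the usual protein partial specific volume of ~0.73 cm^3/g at
#' typical contour levels).
#'
#' @param volume_nm3 volume in nm^3.
#' @param nm3_per_kda conversion constant, nm^3 per kDa.
#' @return mass in kDa.
#' @export
volume_to_mass <- function(volume_nm3, nm3_per_kda = 1.212) {
  if (any(volume_nm3 < 0)) stop("negative volume")
  if (nm3_per_kda <= 0) stop("conversion constant must be > 0")
  volume_nm3 / nm3_per_kda
}

#' Inverse conversion: mass to expected density volume
#' @param mass_kda mass in kDa.
#' @inheritParams volume_to_mass
#' @return volume in nm^3.
#' @export
mass_to_volume <- function(mass_kda, nm3_per_kda = 1.212) {
  if (any(mass_kda < 0)) stop("negative mass")
  mass_kda * nm3_per_kda
}
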