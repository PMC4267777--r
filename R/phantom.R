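## Synthetic-data generator: virion / procapsid / packaging-mutant density
## phantoms and simulated projection stacks with ground truth.

#' Phantom specification
#'
#' Full parameterization of a synthetic membrane-containing icosahedral
#' virion. All lengths are in Angstrom at full scale; `scale_factor`
#' shrinks the whole geometry (radii, channel, jitter) so that desk-scale
#' boxes keep geometric fidelity. Radial shells have a raised-cosine
#' cross-section whose full width at half maximum equals exactly the stated
#' (inner, outer) extent, so shell radii measured from the phantom by
#' [fwhm_extent()] recover the specification.
#'
#' The unique vertex is planted along vertex axis 1 of
#' [icosahedral_group()]: the penton/peripentonal capsid density is carved
#' out of a cone of half-angle `carve_half_angle` (when `vertex_carved`),
#' and replaced by an external portal cylinder with exact `portal_fold`
#' rotational symmetry (when `portal_present`) and a transmembrane conduit
#' with exact `conduit_fold` symmetry enclosing an empty axial channel of
#' `channel_width` (when `conduit_present`).
#'
#' @param box_size box side in voxels (even).
#' @param voxel_size voxel size in Angstrom.
#' @param scale_factor global geometry shrink factor.
#' @param capsid_radii FWHM (inner, outer) extent of the capsid shell, A.
#' @param capsid_amplitude shell amplitude (arbitrary density units).
#' @param membrane_radii FWHM (inner, outer) extent of the lipid shell, A.
#' @param membrane_amplitude_scale membrane amplitude as a fraction of the
#'   capsid amplitude (the "relative membrane intensity" of the state).
#' @param membrane_disorder_sigma per-particle radial jitter of the
#'   membrane shell, A (standard deviation; 0 = rigid membrane).
#' @param facet_modulation 0-1 icosahedral faceting strength (0 = spherical
#'   shells).
#' @param vertex_carved replace the penton + peripentonal density at the
#'   unique vertex by a void (all particle states of this system keep the
#'   carved vertex; set FALSE only for a fully regular control phantom).
#' @param carve_half_angle half-angle of the carved cone, degrees.
#' @param portal_present,portal_fold,portal_radial_extent,portal_cyl_radius
#'   external portal: presence, exact rotational symmetry (default 12-fold),
#'   radial extent (A from the particle centre) and cylinder radius (A).
#' @param conduit_present,conduit_fold,conduit_radial_extent,conduit_cyl_radius
#'   transmembrane conduit: presence, exact symmetry (default 6-fold),
#'   radial extent and cylinder radius.
#' @param channel_width width of the empty axial genome channel, A.
#' @param internal_density_present generic filled core standing in for the
#'   packaged genome (a qualitative proxy only).
#' @param internal_amplitude core amplitude relative to the capsid.
#' @param spikes_present decorate the 11 regular vertices with Gaussian
#'   spike densities (the receptor-binding complexes of the regular
#'   five-fold vertices). Off by default -- the real complexes are flexible
#'   and unresolved -- but they pin the icosahedral orientation of
#'   simulated particles, which otherwise have a single angular feature.
#'   Each spike is displaced tangentially off its vertex axis
#'   (`spike_offset`): like a real protein decoration, the constellation is
#'   chiral, which breaks the accidental centrosymmetry of a phantom built
#'   purely from axisymmetric parts (a centrosymmetric reference cannot
#'   distinguish a pose from its 180-degree in-plane flip).
#' @param spike_radius,spike_sigma,spike_amplitude,spike_offset spike
#'   centre radius (A), width (A), amplitude (relative to the capsid) and
#'   tangential off-axis displacement (A).
#' @param capsomer_texture add an icosahedrally symmetric quasi-random
#'   bump texture over the capsid shell (a stand-in for the capsomer
#'   lattice of a real capsid): `texture_points` deterministic positions in
#'   one asymmetric unit, replicated by all 60 rotations. The texture is
#'   part of the capsid and identical in the phantom and its symmetrized
#'   reference; like a real protein shell it is chiral and makes the
#'   orientation of a projection well determined. Off by default.
#' @param texture_points,texture_sigma,texture_amplitude number of bumps
#'   per asymmetric unit, bump width (A) and amplitude (relative to the
#'   capsid).
#' @param supersample antialiasing factor: the phantom is evaluated on a
#'   `supersample`-times finer grid and block-averaged down, suppressing
#'   the grid-locked aliasing of shells only a few voxels thick.
#' @param shift_max simulation bound for 2-D origin shifts, A.
#' @param state particle state label recorded in ground truth.
#' @param seed default RNG seed for [simulate_stack()].
#' @return object of class `phantom_spec`.
#' @seealso [virion_spec()], [procapsid_spec()], [sus_spec()]
#' @export
phantom_spec <- function(box_size = 96, voxel_size = 5, scale_factor = 0.5,
                         capsid_radii = c(283, 322), capsid_amplitude = 1,
                         membrane_radii = c(223, 260),
                         membrane_amplitude_scale = 1,
                         membrane_disorder_sigma = 0,
                         facet_modulation = 0,
                         vertex_carved = TRUE, carve_half_angle = 20,
                         portal_present = TRUE, portal_fold = 12,
                         portal_radial_extent = c(285, 335),
                         portal_cyl_radius = 65,
                         conduit_present = TRUE, conduit_fold = 6,
                         conduit_radial_extent = c(205, 290),
                         conduit_cyl_radius = 65,
                         channel_width = 45,
                         internal_density_present = FALSE,
                         internal_amplitude = 0.3,
                         spikes_present = FALSE,
                         spike_radius = 355, spike_sigma = 35,
                         spike_amplitude = 1, spike_offset = 40,
                         capsomer_texture = FALSE,
                         texture_points = 20, texture_sigma = 14,
                         texture_amplitude = 0.8,
                         supersample = 2,
                         shift_max = 5,
                         state = "virion",
                         seed = 1) {
  spec <- structure(as.list(environment()), class = "phantom_spec")
  validate_phantom_spec(spec)
  spec
}

validate_phantom_spec <- function(spec) {
  with(spec, {
    if (box_size %% 2 != 0 || box_size < 16) stop("box_size must be even and >= 16")
    for (p in list(capsid_radii, membrane_radii, portal_radial_extent,
                   conduit_radial_extent)) {
      if (length(p) != 2 || p[1] >= p[2])
        stop("radius pairs must be ordered (inner < outer)")
    }
    if (capsid_radii[2] * scale_factor >= box_size * voxel_size / 2)
      stop("box too small for phantom: outer capsid radius exceeds half box")
    if (portal_present &&
        portal_radial_extent[2] * scale_factor >= box_size * voxel_size / 2)
      stop("box too small for phantom: portal exceeds half box")
    if (channel_width >= 2 * conduit_cyl_radius)
      stop("channel_width must be smaller than the conduit diameter")
    if (portal_fold < 1 || conduit_fold < 1) stop("symmetry folds must be >= 1")
    if (facet_modulation < 0 || facet_modulation > 1)
      stop("facet_modulation must be in [0, 1]")
    if (membrane_disorder_sigma < 0) stop("membrane_disorder_sigma must be >= 0")
    if (!supersample %in% 1:4) stop("supersample must be 1, 2, 3 or 4")
    if (spikes_present &&
        (spike_radius + spike_offset + 2 * spike_sigma) * scale_factor >=
          box_size * voxel_size / 2)
      stop("box too small for phantom: spikes exceed half box")
  })
  invisible(spec)
}

#' @export
print.phantom_spec <- function(x, ...) {
  cat(sprintf("phantom_spec (%s): box %d^3 @ %.2f A, scale %.2f\n",
              x$state, x$box_size, x$voxel_size, x$scale_factor))
  cat(sprintf("  capsid %g-%g A (amp %g); membrane %g-%g A (x%.2f, jitter %g A)\n",
              x$capsid_radii[1], x$capsid_radii[2], x$capsid_amplitude,
              x$membrane_radii[1], x$membrane_radii[2],
              x$membrane_amplitude_scale, x$membrane_disorder_sigma))
  cat(sprintf("  portal: %s (C%d); conduit: %s (C%d, channel %g A); carved vertex: %s\n",
              if (x$portal_present) "on" else "off", x$portal_fold,
              if (x$conduit_present) "on" else "off", x$conduit_fold,
              x$channel_width, x$vertex_carved))
  invisible(x)
}

#' Convenience phantom states
#'
#' Preset specifications mirroring the particle states of the system: the
#' mature virion (portal + conduit + packed core, rigid membrane at 100%
#' intensity), the procapsid (conduit but no portal, genome-free, slightly
#' expanded membrane at 80%), and a Sus42-like packaging mutant (no portal,
#' no conduit, disordered weak membrane at 62%).
#'
#' @param ... overrides passed to [phantom_spec()].
#' @rdname phantom_states
#' @export
virion_spec <- function(...) {
  state_spec(list(state = "virion", internal_density_present = TRUE), ...)
}

#' @rdname phantom_states
#' @export
procapsid_spec <- function(...) {
  state_spec(list(state = "procapsid", portal_present = FALSE,
                  capsid_radii = c(281, 322), membrane_radii = c(200, 245),
                  membrane_amplitude_scale = 0.8,
                  internal_density_present = FALSE), ...)
}

#' @rdname phantom_states
#' @export
sus_spec <- function(...) {
  state_spec(list(state = "sus-like", portal_present = FALSE,
                  conduit_present = FALSE,
                  capsid_radii = c(281, 328), membrane_radii = c(203, 240),
                  membrane_amplitude_scale = 0.62,
                  membrane_disorder_sigma = 10,
                  internal_density_present = FALSE), ...)
}

## state defaults overridable by user arguments
state_spec <- function(defaults, ...) {
  args <- utils::modifyList(defaults, list(...))
  do.call(phantom_spec, args)
}

## raised-cosine radial shell: FWHM extent is exactly [rin, rout]
shell_profile <- function(r, rin, rout, amp = 1) {
  rc <- (rin + rout) / 2
  h <- rout - rin
  out <- amp * 0.5 * (1 + cos(pi * (r - rc) / h))
  out[abs(r - rc) >= h] <- 0
  out
}

## soft ball: 1 inside R - edge, cosine taper to 0 at R
ball_profile <- function(r, R, edge) {
  out <- numeric(length(r))
  out[r <= R - edge] <- 1
  sel <- r > R - edge & r < R
  out[sel] <- 0.5 * (1 + cos(pi * (r[sel] - (R - edge)) / edge))
  out
}

## smooth step from 0 (x <= 0) to 1 (x >= 1)
smoothstep <- function(x) {
  x <- pmin(1, pmax(0, x))
  x * x * (3 - 2 * x)
}

## local orthonormal frame (u, v) perpendicular to a unit axis
axis_frame <- function(a) {
  ref <- if (abs(a[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  u <- ref - sum(ref * a) * a
  u <- u / sqrt(sum(u^2))
  v <- c(a[2] * u[3] - a[3] * u[2],
         a[3] * u[1] - a[1] * u[3],
         a[1] * u[2] - a[2] * u[1])
  list(u = u, v = v)
}

## block-average a cubic array by an integer factor
bin_axis1 <- function(a, os) {
  d <- dim(a)
  array(colSums(matrix(a, nrow = os)), c(d[1] / os, d[2], d[3]))
}

bin_down <- function(arr, os) {
  if (os == 1) return(arr)
  a <- bin_axis1(arr, os)
  a <- aperm(bin_axis1(aperm(a, c(2, 1, 3)), os), c(2, 1, 3))
  a <- aperm(bin_axis1(aperm(a, c(3, 2, 1)), os), c(3, 2, 1))
  a / os^3
}

## centred coordinate axes of the supersampled grid, in fine-voxel units:
## fine voxel j sits at j - (n/2 + (os - 1)/2), so that os^3 blocks average
## to the coarse grid's centre convention
coord_arrays_offset <- function(n, os) {
  x <- seq_len(n) - 1 - (n / 2 + (os - 1) / 2)
  ax <- array(x, c(n, n, n))
  list(x = ax, y = aperm(ax, c(2, 1, 3)), z = aperm(ax, c(3, 2, 1)))
}

## spike centres (3 x 11, Angstrom at full scale): one per regular vertex,
## displaced tangentially so the constellation is chiral
spike_positions <- function(spec) {
  axes <- icosahedral_group()$vertex_axes
  vref <- c(0.1234, 0.4567, 0.8810)
  vref <- vref / sqrt(sum(vref^2))
  P <- matrix(0, 3, 11)
  for (w in 2:12) {
    a <- axes[, w]
    u <- c(a[2] * vref[3] - a[3] * vref[2],
           a[3] * vref[1] - a[1] * vref[3],
           a[1] * vref[2] - a[2] * vref[1])
    u <- u / sqrt(sum(u^2))
    P[, w - 1] <- a * spec$spike_radius + u * spec$spike_offset
  }
  P
}

## deterministic capsomer-texture centres (Angstrom, full scale): the
## first `texture_points` Fibonacci-sphere directions inside the canonical
## asymmetric unit, at radii spread across the capsid shell; the full
## texture is their orbit under the 60 rotations
texture_positions <- function(spec) {
  D <- asym_unit_directions(2)
  k <- min(spec$texture_points, ncol(D))
  D <- D[, seq_len(k), drop = FALSE]
  gr <- (sqrt(5) - 1) / 2
  rmid <- mean(spec$capsid_radii)
  half <- diff(spec$capsid_radii) / 2
  radii <- rmid + (((seq_len(k) * gr) %% 1) - 0.5) * half
  P <- sweep(D, 2, radii, "*")
  orbit <- do.call(cbind, lapply(icosahedral_group()$rotations,
                                 function(G) G %*% P))
  orbit
}

## accumulate Gaussian blobs (separable windowed evaluation on the fine
## grid; `base` has the fine-grid dimensions)
add_gaussians <- function(base, spec, centers, sigma, amp) {
  os <- spec$supersample
  n <- spec$box_size * os
  vxf <- spec$voxel_size / os
  ax <- (seq_len(n) - 1 - (n / 2 + (os - 1) / 2)) * vxf
  dim(base) <- rep(n, 3)
  for (j in seq_len(ncol(centers))) {
    ctr <- centers[, j]
    rng <- lapply(1:3, function(k) which(abs(ax - ctr[k]) < 4 * sigma))
    if (any(lengths(rng) == 0)) next
    d1 <- (ax[rng[[1]]] - ctr[1])^2
    d2 <- (ax[rng[[2]]] - ctr[2])^2
    d3 <- (ax[rng[[3]]] - ctr[3])^2
    g <- amp * exp(-outer(outer(d1, d2, "+"), d3, "+") / (2 * sigma^2))
    base[rng[[1]], rng[[2]], rng[[3]]] <-
      base[rng[[1]], rng[[2]], rng[[3]]] + g
  }
  base
}

## geometry fields reused across per-particle membrane rebuilds, evaluated
## on the supersampled grid
phantom_fields <- function(spec) {
  n <- spec$box_size * spec$supersample
  co <- coord_arrays_offset(n, spec$supersample)
  x <- co$x * spec$voxel_size / spec$supersample
  y <- co$y * spec$voxel_size / spec$supersample
  z <- co$z * spec$voxel_size / spec$supersample
  r <- sqrt(x^2 + y^2 + z^2)
  a <- icosahedral_group()$vertex_axes[, 1]
  h <- x * a[1] + y * a[2] + z * a[3]      # signed distance along vertex axis
  rho2 <- pmax(r^2 - h^2, 0)
  rho <- sqrt(rho2)                        # distance from the vertex axis
  fr <- axis_frame(a)
  phi <- atan2(x * fr$v[1] + y * fr$v[2] + z * fr$v[3],
               x * fr$u[1] + y * fr$u[2] + z * fr$u[3])
  list(r = r, h = h, rho = rho, phi = phi, x = x, y = y, z = z, axis = a)
}

## icosahedral faceting: shrink the effective radius on facets
facet_radius <- function(r, x, y, z, strength) {
  if (strength <= 0) return(r)
  gr <- (1 + sqrt(5)) / 2
  ## the 20 face axes of the icosahedron (vertex-sum directions)
  v <- icosahedral_group()$vertex_axes
  ## faces = triples of mutually adjacent vertices; approximate face axes by
  ## normalizing all distinct sums of vertex pairs' cross pattern is overkill:
  ## use the dual dodecahedron vertices (+-1,+-1,+-1), (0,+-1/gr,+-gr), ...
  f <- cbind(expand_signs(c(1, 1, 1)),
             expand_signs(c(0, 1 / gr, gr)),
             expand_signs(c(1 / gr, gr, 0)),
             expand_signs(c(gr, 0, 1 / gr)))
  f <- f / sqrt(colSums(f^2))
  rr <- pmax(r, 1e-9)
  g <- 0
  for (i in seq_len(ncol(f))) {
    g <- pmax(g, (x * f[1, i] + y * f[2, i] + z * f[3, i]) / rr)
  }
  ## g in [cos(face half-angle), 1]; scale radius so facets flatten
  r * (1 - strength * (1 - g) / (1 - min(g)))
}

#' Build a density phantom
#'
#' Deterministic given the specification; the RNG is untouched. The
#' optional `membrane_offset` (A, full scale) shifts the membrane shell
#' radially and is how [simulate_stack()] applies per-particle membrane
#' disorder.
#'
#' @param spec a [phantom_spec()].
#' @param membrane_offset radial membrane displacement in A (full scale).
#' @return a [volume3d()].
#' @export
build_phantom <- function(spec, membrane_offset = 0) {
  validate_phantom_spec(spec)
  f <- phantom_fields(spec)
  parts <- phantom_parts(spec, f)
  vol <- parts$base + parts$membrane_at(membrane_offset)
  volume3d(vol, spec$voxel_size)
}

## split the phantom into a fixed part and a membrane builder so that
## per-particle membrane jitter does not rebuild everything
phantom_parts <- function(spec, f = phantom_fields(spec)) {
  s <- spec$scale_factor
  vx <- spec$voxel_size
  edge <- 2 * vx                                  # smoothing edge, A

  capsid_r <- if (spec$facet_modulation > 0) {
    facet_radius(f$r, f$x, f$y, f$z, spec$facet_modulation * 0.15)
  } else f$r
  base <- shell_profile(capsid_r, spec$capsid_radii[1] * s,
                        spec$capsid_radii[2] * s, spec$capsid_amplitude)

  if (spec$vertex_carved) {
    ang <- acos(pmin(1, pmax(-1, f$h / pmax(f$r, 1e-9))))
    keep <- smoothstep((rad2deg(ang) - spec$carve_half_angle) / 4)
    base <- base * keep
  }

  lobes <- function(fold, phi) 0.5 + 0.5 * cos(fold * phi)

  if (spec$portal_present) {
    reg <- f$h > 0 &
      f$r >= spec$portal_radial_extent[1] * s &
      f$r <= spec$portal_radial_extent[2] * s &
      f$rho < spec$portal_cyl_radius * s &
      f$rho >= spec$channel_width / 2 * s
    portal <- numeric(length(f$r))
    portal[reg] <- spec$capsid_amplitude * lobes(spec$portal_fold, f$phi[reg])
    base <- base + portal
  }

  if (spec$conduit_present) {
    reg <- f$h > 0 &
      f$r >= spec$conduit_radial_extent[1] * s &
      f$r <= spec$conduit_radial_extent[2] * s &
      f$rho < spec$conduit_cyl_radius * s &
      f$rho >= spec$channel_width / 2 * s
    conduit <- numeric(length(f$r))
    conduit[reg] <- spec$capsid_amplitude * lobes(spec$conduit_fold, f$phi[reg])
    base <- base + conduit
  }

  if (spec$internal_density_present) {
    core <- ball_profile(f$r, (spec$membrane_radii[1] - 15) * s, 20 * s)
    base <- base + spec$internal_amplitude * spec$capsid_amplitude * core
  }

  if (spec$spikes_present) {
    base <- add_gaussians(base, spec, spike_positions(spec) * s,
                          spec$spike_sigma * s,
                          spec$spike_amplitude * spec$capsid_amplitude)
  }

  if (spec$capsomer_texture) {
    base <- add_gaussians(base, spec, texture_positions(spec) * s,
                          spec$texture_sigma * s,
                          spec$texture_amplitude * spec$capsid_amplitude)
  }

  ## membrane opening at the conduit so that the channel crosses the bilayer
  mem_hole <- if (spec$conduit_present) {
    1 - (f$h > 0) * (1 - smoothstep((f$rho - spec$conduit_cyl_radius * s) / edge))
  } else 1

  nf <- spec$box_size * spec$supersample
  dim(base) <- rep(nf, 3)
  membrane_at_fine <- function(offset = 0) {
    m <- shell_profile(
      f$r,
      (spec$membrane_radii[1] + offset) * s,
      (spec$membrane_radii[2] + offset) * s,
      spec$capsid_amplitude * spec$membrane_amplitude_scale
    ) * mem_hole
    dim(m) <- rep(nf, 3)
    m
  }
  list(base_fine = base, membrane_at_fine = membrane_at_fine,
       base = bin_down(base, spec$supersample),
       membrane_at = function(offset = 0)
         bin_down(membrane_at_fine(offset), spec$supersample))
}

## 2x2 block average of a (2N x 2N) image
bin_image2 <- function(img) {
  n2 <- nrow(img)
  a <- matrix(colSums(matrix(img, nrow = 2)), n2 / 2, n2)
  t(matrix(colSums(matrix(t(a), nrow = 2)), n2 / 2, n2 / 2)) / 4
}

## project the supersampled phantom and bin the projection: the aliasing of
## real-space scattering on the coarse grid would otherwise leave a
## per-pose artifact pattern comparable to the faint attachment signal.
## The half-voxel offsets compensate the fine grid's centre convention so
## the binned image obeys the coarse one.
project_supersampled <- function(vol_fine, spec, R, sx_A, sy_A) {
  os <- spec$supersample
  nf <- spec$box_size * os
  vxf <- spec$voxel_size / os
  off <- -(os - 1) / 2
  dhalf <- (os - 1) / 2
  img <- cpp_project(vol_fine, R, rep(off, 3), nf,
                     sx_A / vxf + dhalf, sy_A / vxf + dhalf)
  if (os == 1) return(img)
  if (os != 2) stop("supersampled projection supports factors 1 and 2")
  bin_image2(img) / os          # keep line-integral normalization
}

#' Analytically symmetrized phantom
#'
#' The exact icosahedral-group average of [build_phantom()], evaluated in
#' closed form: the spherical shells are already invariant, and each
#' vertex-anchored term (carved cone, membrane opening, portal, conduit)
#' is replaced by its axisymmetric azimuthal average placed at all 12
#' vertex axes with weight 1/12. Because the portal/conduit folds are
#' coprime to 5, the five-fold vertex average removes the angular
#' modulation exactly, leaving the annular envelope scaled by the mean
#' squared lobe profile (3/8). Unlike [symmetrize_icos()] applied to a
#' sampled map, this construction carries no resampling artifacts, which
#' makes it the reference of choice for orientation determination on
#' phantom data.
#'
#' @param spec a [phantom_spec()].
#' @return a [volume3d()].
#' @export
build_phantom_symmetrized <- function(spec) {
  validate_phantom_spec(spec)
  s <- spec$scale_factor
  vx <- spec$voxel_size
  edge <- 2 * vx
  f <- phantom_fields(spec)
  axes <- icosahedral_group()$vertex_axes

  capsid_r <- if (spec$facet_modulation > 0) {
    facet_radius(f$r, f$x, f$y, f$z, spec$facet_modulation * 0.15)
  } else f$r
  capsid <- shell_profile(capsid_r, spec$capsid_radii[1] * s,
                          spec$capsid_radii[2] * s, spec$capsid_amplitude)
  membrane <- shell_profile(f$r, spec$membrane_radii[1] * s,
                            spec$membrane_radii[2] * s,
                            spec$capsid_amplitude * spec$membrane_amplitude_scale)
  nf <- spec$box_size * spec$supersample
  out <- array(0, rep(nf, 3))
  lobes_mean <- 0.5                         # mean of 1/2 + cos(k phi)/2
  for (w in seq_len(12)) {
    a <- axes[, w]
    h <- f$x * a[1] + f$y * a[2] + f$z * a[3]
    rho <- sqrt(pmax(f$r^2 - h^2, 0))
    if (spec$vertex_carved) {
      ang <- acos(pmin(1, pmax(-1, h / pmax(f$r, 1e-9))))
      capsid <- capsid *
        (1 - (1 - smoothstep((rad2deg(ang) - spec$carve_half_angle) / 4)) / 12)
    }
    if (spec$conduit_present) {
      hole <- (h > 0) * (1 - smoothstep((rho - spec$conduit_cyl_radius * s) / edge))
      membrane <- membrane * (1 - hole / 12)
      reg <- h > 0 &
        f$r >= spec$conduit_radial_extent[1] * s &
        f$r <= spec$conduit_radial_extent[2] * s &
        rho < spec$conduit_cyl_radius * s &
        rho >= spec$channel_width / 2 * s
      out <- out + reg * (spec$capsid_amplitude * lobes_mean / 12)
    }
    if (spec$portal_present) {
      reg <- h > 0 &
        f$r >= spec$portal_radial_extent[1] * s &
        f$r <= spec$portal_radial_extent[2] * s &
        rho < spec$portal_cyl_radius * s &
        rho >= spec$channel_width / 2 * s
      out <- out + reg * (spec$capsid_amplitude * lobes_mean / 12)
    }
  }
  if (spec$spikes_present) {
    ## exact group average of the spike constellation: the orbit of the 11
    ## spike centres under the 60 rotations, weight 1/60 each
    P <- spike_positions(spec) * s
    orbit <- do.call(cbind, lapply(icosahedral_group()$rotations,
                                   function(G) G %*% P))
    out <- add_gaussians(out, spec, orbit, spec$spike_sigma * s,
                         spec$spike_amplitude * spec$capsid_amplitude / 60)
  }
  if (spec$capsomer_texture) {
    out <- add_gaussians(out, spec, texture_positions(spec) * s,
                         spec$texture_sigma * s,
                         spec$texture_amplitude * spec$capsid_amplitude)
  }
  out <- out + capsid + membrane
  if (spec$internal_density_present) {
    out <- out + spec$internal_amplitude * spec$capsid_amplitude *
      ball_profile(f$r, (spec$membrane_radii[1] - 15) * s, 20 * s)
  }
  dim(out) <- rep(nf, 3)
  volume3d(bin_down(out, spec$supersample), vx)
}

#' Simulate a noisy projection stack with ground truth
#'
#' Each particle is drawn with a uniform random orientation and a uniform
#' 2-D origin shift within `spec$shift_max`, projected with the central
#' slice projector, and corrupted with white Gaussian noise scaled so that
#' the ratio of signal variance (within the circular particle support of
#' radius = scaled outer capsid radius) to noise variance equals `snr`.
#' Per-particle membrane jitter is applied when
#' `spec$membrane_disorder_sigma > 0`. Bit-reproducible for a fixed seed.
#'
#' @param spec a [phantom_spec()].
#' @param n_particles number of particles (>= 1).
#' @param snr signal-to-noise variance ratio; `Inf` for noiseless.
#' @param seed RNG seed (defaults to `spec$seed`).
#' @return list with `stack` (a [particle_stack()]), `truth` (ground-truth
#'   data.frame: id, true ZYZ Euler angles phi/theta/psi in degrees, shifts
#'   sx/sy in A, true `candidate_idx` among the 60 icosahedral candidates
#'   (1-based), the canonical icosahedral pose `icos_phi/theta/psi`, and the
#'   particle `state`), and `spec`.
#' @export
simulate_stack <- function(spec, n_particles, snr = Inf, seed = spec$seed) {
  validate_phantom_spec(spec)
  if (n_particles < 1) stop("n_particles must be >= 1")
  if (!(snr > 0)) stop("snr must be > 0 (use Inf for noiseless)")
  set.seed(seed)
  n <- spec$box_size
  vx <- spec$voxel_size
  parts <- phantom_parts(spec)
  static_membrane <- spec$membrane_disorder_sigma == 0
  if (static_membrane) vol0 <- parts$base_fine + parts$membrane_at_fine(0)

  ## circular particle support for the SNR definition
  k <- freq_axis(n)
  supp <- outer(k, k, function(a, b) sqrt(a^2 + b^2)) * vx <=
    spec$capsid_radii[2] * spec$scale_factor

  rots <- random_rotations(n_particles)
  shifts <- matrix(stats::runif(2 * n_particles, -spec$shift_max,
                                spec$shift_max), ncol = 2)
  mem_off <- if (static_membrane) numeric(n_particles) else
    stats::rnorm(n_particles, 0, spec$membrane_disorder_sigma)

  images <- array(0, c(n, n, n_particles))
  truth <- vector("list", n_particles)
  for (i in seq_len(n_particles)) {
    vol <- if (static_membrane) vol0 else
      parts$base_fine + parts$membrane_at_fine(mem_off[i])
    img <- project_supersampled(vol, spec, rots[[i]],
                                shifts[i, 1], shifts[i, 2])
    if (is.finite(snr)) {
      sdn <- sqrt(stats::var(as.numeric(img[supp])) / snr)
      img <- img + array(stats::rnorm(n * n, 0, sdn), c(n, n))
    }
    images[, , i] <- img
    cp <- canonical_icos_pose(rots[[i]])
    eul <- matrix_to_euler(rots[[i]])
    ieul <- matrix_to_euler(cp$R)
    truth[[i]] <- data.frame(
      id = i - 1L, phi = eul[1], theta = eul[2], psi = eul[3],
      sx = shifts[i, 1], sy = shifts[i, 2],
      candidate_idx = cp$candidate_index,
      icos_phi = ieul[1], icos_theta = ieul[2], icos_psi = ieul[3],
      state = spec$state
    )
  }
  truth <- do.call(rbind, truth)
  rownames(truth) <- NULL
  list(stack = particle_stack(images, vx), truth = truth, spec = spec)
}
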