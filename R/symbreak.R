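## Resolving the 60-fold icosahedral ambiguity: masked-library scoring of
## the unique vertex, the regular-vertex anchoring mode, and the iterative
## refinement loop.
##
## An icosahedrally determined pose leaves 60 equivalent choices for where a
## vertex-anchored asymmetric feature sits: 12 vertex locations x 5
## attachments at a 5-fold. Candidates are enumerated as {R %*% G} over the
## group, scored against projections of a masked 3-D vertex model, and the
## assignment refined by alternating with unsymmetrized reconstruction.

#' Enumerate the 60 icosahedrally equivalent candidate poses
#'
#' @param icos_pose a [pose()] (or 3x3 rotation matrix) within the
#'   icosahedral asymmetric unit.
#' @param group an [icosahedral_group()].
#' @return object of class `candidate_set`: list with `rotations` (60
#'   matrices `R %*% G_j`), `sx`, `sy` (shared shifts, Angstrom), and
#'   `group`. Scores are added by [score_candidates()].
#' @export
enumerate_candidates <- function(icos_pose, group = icosahedral_group()) {
  if (inherits(icos_pose, "pose")) {
    R <- pose_matrix(icos_pose)
    sx <- icos_pose$sx; sy <- icos_pose$sy
  } else {
    R <- icos_pose; sx <- 0; sy <- 0
  }
  rots <- lapply(group$rotations, function(g) R %*% g)
  ## degenerate-input guard: candidates must be pairwise distinct
  keys <- vapply(rots, mat_key, "")
  if (anyDuplicated(keys))
    stop("degenerate pose: fewer than 60 distinct candidates")
  structure(list(rotations = rots, sx = sx, sy = sy, group = group),
            class = "candidate_set")
}

#' @export
print.candidate_set <- function(x, ...) {
  cat(sprintf("candidate_set: %d candidate poses\n", length(x$rotations)))
  if (!is.null(x$scores)) {
    cat(sprintf("  best index %d (score %.4f, margin %.4f%s)\n",
                x$best_index, x$scores[x$best_index], x$margin,
                if (x$ambiguous) ", AMBIGUOUS" else ""))
  }
  invisible(x)
}

#' Extract a vertex model from a map
#'
#' Builds the 3-D vertex mask (a cone of `half_angle` degrees about vertex
#' axis 1 of the icosahedral group, restricted to the stated radial extent)
#' and the masked, thresholded density. The default threshold is the "very
#' low density threshold" used to seed the asymmetric search: map mean +
#' `threshold_sigma` standard deviations. The model is stored cropped to
#' its bounding box for fast projection.
#'
#' @param map a [volume3d()].
#' @param radial_extent numeric (inner, outer) radial extent in Angstrom
#'   (at the map's scale).
#' @param half_angle cone half-angle about the vertex axis, degrees.
#' @param threshold density threshold; `NULL` for mean + `threshold_sigma`
#'   x sd.
#' @param threshold_sigma multiplier for the automatic threshold.
#' @param mode `"unique-vertex"` or `"regular-vertex"` tag.
#' @param background `"radial"` subtracts the map's spherical (shell)
#'   average before segmenting, so the model captures the vertex feature
#'   rather than the capsid/membrane shells that every candidate shares
#'   (the default for the unique-vertex mode); `"none"` keeps the raw
#'   density (the default for the regular-vertex mode, whose signal is the
#'   presence of the penton shell itself).
#' @param background_map optional [volume3d()] subtracted from `map` before
#'   segmentation (overrides `background`): typically the icosahedrally
#'   symmetrized map, leaving exactly the symmetry-breaking residual.
#' @return object of class `vertex_model`.
#' @export
vertex_model <- function(map, radial_extent, half_angle = 25,
                         threshold = NULL, threshold_sigma = 0.5,
                         mode = "unique-vertex",
                         background = if (mode == "unique-vertex")
                           "radial" else "none",
                         background_map = NULL) {
  n <- dim(map$data)[1]
  vx <- map$voxel
  co <- coord_arrays(n)
  a <- icosahedral_group()$vertex_axes[, 1]
  r <- sqrt(co$x^2 + co$y^2 + co$z^2) * vx
  h <- (co$x * a[1] + co$y * a[2] + co$z * a[3]) * vx
  ang <- rad2deg(acos(pmin(1, pmax(-1, h / pmax(r, 1e-9)))))
  mask <- ang <= half_angle & r >= radial_extent[1] & r <= radial_extent[2]
  if (!any(mask)) stop("vertex mask is empty")
  dat <- map$data
  if (!is.null(background_map)) {
    stopifnot_same_grid(map, background_map)
    dat <- dat - background_map$data
    background <- "map"
  } else if (background == "radial") {
    rb <- round(sqrt(co$x^2 + co$y^2 + co$z^2)) + 1L
    m <- as.numeric(tapply(dat, rb, mean))
    dat <- dat - array(m[as.integer(rb)], dim(dat))
  }
  if (is.null(threshold))
    threshold <- mean(dat) + threshold_sigma * stats::sd(dat)
  ## a residual-based model keeps both signs: the unique vertex shows up as
  ## the missing penton/peripentonal density (negative residual) plus the
  ## portal/conduit density (positive); a raw-density model keeps the
  ## segmented positive feature only
  dens <- if (background %in% c("radial", "map")) {
    dat * mask * (abs(dat) >= threshold)
  } else {
    dat * mask * (dat >= threshold)
  }

  idx <- which(mask, arr.ind = TRUE)
  lo <- pmax(apply(idx, 2, min) - 1L, 1L)
  hi <- pmin(apply(idx, 2, max) + 1L, n)
  ## keep the crop even-sized so its own centre convention stays consistent
  size <- hi - lo + 1L
  size <- size + size %% 2L
  hi <- pmin(lo + size - 1L, n)
  lo <- hi - size + 1L
  crop <- function(x) x[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE]
  cc_full <- n %/% 2              # 0-based centre of the full box
  cc_crop <- (lo - 1L) + size %/% 2
  ## cubic sub-box around the model support for the Fourier projector:
  ## artifact-free template projections at a fraction of the full-box cost
  ctr <- round((lo + hi) / 2)
  L <- ceiling(sqrt(sum((hi - lo + 1)^2))) + 4L
  L <- min(L + L %% 2, n)
  cube <- array(0, c(L, L, L))
  src_lo <- pmax(ctr - L %/% 2, 1L)
  src_hi <- pmin(ctr + L %/% 2 - 1L, n)
  dst_lo <- src_lo - (ctr - L %/% 2) + 1L
  dst_hi <- dst_lo + (src_hi - src_lo)
  cube[dst_lo[1]:dst_hi[1], dst_lo[2]:dst_hi[2], dst_lo[3]:dst_hi[3]] <-
    dens[src_lo[1]:src_hi[1], src_lo[2]:src_hi[2], src_lo[3]:src_hi[3]]

  structure(list(
    density = crop(dens), mask = crop(mask * 1),
    offset = cc_crop - cc_full,   # crop centre relative to full centre
    box = n, voxel = vx, axis = a, mode = mode,
    half_angle = half_angle, radial_extent = radial_extent,
    threshold = threshold, background = background,
    projector = fourier_projector(volume3d(cube, vx)),
    cube_offset = (ctr - 1) - n %/% 2  # cube centre rel. full centre
  ), class = "vertex_model")
}

#' @export
print.vertex_model <- function(x, ...) {
  cat(sprintf("vertex_model (%s): crop %s, %d voxels in mask, threshold %.4g\n",
              x$mode, paste(dim(x$density), collapse = "x"),
              sum(x$mask > 0), x$threshold))
  invisible(x)
}

## project a vertex model at rotation R into an N x N image: density via
## the cubic-crop Fourier projector (accurate) or real-space scatter of
## the crop (fast); mask support always via scatter
project_model <- function(model, R, sx_px = 0, sy_px = 0, what = "density",
                          fourier = TRUE) {
  if (what == "density" && fourier && !is.null(model$projector)) {
    n <- model$box
    L <- model$projector$n
    ## position of the sub-box centre in the image plane
    q <- (R %*% model$cube_offset)[1:2] + c(sx_px, sy_px)
    qi <- round(q)
    small <- project_fourier(model$projector, R, q[1] - qi[1], q[2] - qi[2])
    out <- matrix(0, n, n)
    t_lo <- n %/% 2 + qi - L %/% 2 + 1L   # 1-based target range
    t_hi <- t_lo + L - 1L
    s_lo <- pmax(1L - t_lo + 1L, 1L)
    t_lo2 <- pmax(t_lo, 1L)
    t_hi2 <- pmin(t_hi, n)
    if (all(t_hi2 >= t_lo2)) {
      s_hi <- s_lo + (t_hi2 - t_lo2)
      out[t_lo2[1]:t_hi2[1], t_lo2[2]:t_hi2[2]] <-
        small[s_lo[1]:s_hi[1], s_lo[2]:s_hi[2]]
    }
    return(out)
  }
  cpp_project(model[[what]], R, model$offset, model$box, sx_px, sy_px)
}

#' Build the 2-D mask library for the 60 candidates
#'
#' For each candidate pose the 2-D mask is the projected support of the 3-D
#' vertex mask and the model projection is the projected vertex density,
#' both in the particle's image frame (including the particle's shift).
#'
#' @param model a [vertex_model()].
#' @param candidates an (unscored) [enumerate_candidates()] set.
#' @return list with `masks` (60 logical matrices), `projections` (60
#'   numeric matrices).
#' @export
build_mask_library <- function(model, candidates) {
  if (sum(model$mask) == 0) stop("vertex model mask is empty")
  voxel <- model$voxel
  sx <- candidates$sx / model$voxel
  sy <- candidates$sy / model$voxel
  masks <- vector("list", length(candidates$rotations))
  projs <- vector("list", length(candidates$rotations))
  for (j in seq_along(candidates$rotations)) {
    R <- candidates$rotations[[j]]
    mj <- project_model(model, R, sx, sy, "mask") > 0.5
    if (!any(mj)) stop("candidate ", j, " mask projects outside the image")
    masks[[j]] <- mj
    projs[[j]] <- project_model(model, R, sx, sy, "density")
  }
  list(masks = masks, projections = projs, mode = model$mode,
       sx_px = candidates$sx / voxel, sy_px = candidates$sy / voxel)
}

## subtract the circular average about the (shifted) particle centre:
## removes the projected spherical shells, which are identical under every
## candidate and would otherwise drown the vertex feature
whiten_image_about <- function(img, sx_px, sy_px) {
  n <- nrow(img)
  ax <- seq_len(n) - 1 - n %/% 2
  r <- round(sqrt(outer((ax - sx_px)^2, (ax - sy_px)^2, "+"))) + 1L
  m <- as.numeric(tapply(img, r, mean))
  img - array(m[as.integer(r)], dim(img))
}

masked_ncc <- function(image, proj, mask) {
  a <- image[mask]
  b <- proj[mask]
  if (stats::sd(a) == 0 || stats::sd(b) == 0) return(0)
  stats::cor(a, b)
}

## cross-common-lines scorer: correlate central Fourier lines of the masked
## image against those of the model projection
common_lines_score <- function(image, proj, mask, n_lines = 12) {
  n <- nrow(image)
  Fi <- cfft2(image * mask)
  Fm <- cfft2(proj * mask)
  c0 <- n %/% 2 + 1
  rad <- seq(1, n / 2 - 2, by = 0.5)
  angs <- seq(0, pi - pi / n_lines, by = pi / n_lines)
  sample_line <- function(FF, a) {
    x <- pmin(pmax(c0 + rad * cos(a), 1), n - 1)
    y <- pmin(pmax(c0 + rad * sin(a), 1), n - 1)
    ix <- floor(x); iy <- floor(y)
    fx <- x - ix; fy <- y - iy
    FF[cbind(ix, iy)] * (1 - fx) * (1 - fy) +
      FF[cbind(ix + 1, iy)] * fx * (1 - fy) +
      FF[cbind(ix, iy + 1)] * (1 - fx) * fy +
      FF[cbind(ix + 1, iy + 1)] * fx * fy
  }
  vi <- unlist(lapply(angs, function(a) sample_line(Fi, a)))
  vm <- unlist(lapply(angs, function(a) sample_line(Fm, a)))
  x <- c(Re(vi), Im(vi))
  y <- c(Re(vm), Im(vm))
  if (stats::sd(x) == 0 || stats::sd(y) == 0) return(0)
  stats::cor(x, y)
}

#' Score the 60 candidates against the masked vertex library
#'
#' For each candidate, the image region under the candidate's 2-D mask is
#' compared with the model projection: `"masked-ncc"` (default) uses
#' normalized real-space cross-correlation; `"common-lines"` correlates
#' matched central Fourier lines of the masked image and the model
#' projection. Scores lie in `[-1, 1]`; the best index is the argmax with
#' ties broken towards the lowest candidate index. The candidate is flagged
#' ambiguous when the margin (best minus second-best score) falls below
#' `margin_factor` standard deviations of the 59 non-best scores.
#'
#' @param image N x N numeric matrix.
#' @param library from [build_mask_library()].
#' @param candidates the [enumerate_candidates()] set the library was built
#'   from.
#' @param scorer `"masked-ncc"` or `"common-lines"`.
#' @param margin_factor ambiguity criterion multiplier (default 2).
#' @param whiten subtract the circular average about the shifted particle
#'   centre from the image before scoring (default: yes for unique-vertex
#'   models); set `FALSE` when a reference projection has already been
#'   subtracted.
#' @return the candidate set with `scores`, `best_index`, `margin`,
#'   `margin_tol`, `ambiguous` filled in.
#' @export
score_candidates <- function(image, library, candidates,
                             scorer = c("masked-ncc", "common-lines"),
                             margin_factor = 2,
                             whiten = identical(library$mode,
                                                "unique-vertex")) {
  scorer <- match.arg(scorer)
  fun <- if (scorer == "masked-ncc") masked_ncc else common_lines_score
  if (whiten) {
    image <- whiten_image_about(image, library$sx_px, library$sy_px)
  }
  scores <- vapply(seq_along(library$masks), function(j) {
    fun(image, library$projections[[j]], library$masks[[j]])
  }, numeric(1))
  if (any(!is.finite(scores))) scores[!is.finite(scores)] <- 0
  finalize_candidate_scores(candidates, scores, margin_factor)
}

finalize_candidate_scores <- function(candidates, scores, margin_factor,
                                      distinct_groups = NULL) {
  best <- which.max(scores)
  if (is.null(distinct_groups)) {
    srt <- sort(scores, decreasing = TRUE)
    margin <- srt[1] - srt[2]
    tol <- margin_factor * stats::sd(scores[-best])
  } else {
    ## scores degenerate by construction (e.g. 5-fold ties in anchor mode):
    ## margins over the distinct hypothesis values
    u <- tapply(scores, distinct_groups, max)
    srt <- sort(u, decreasing = TRUE)
    margin <- srt[1] - srt[2]
    tol <- margin_factor * stats::sd(u[-which.max(u)])
  }
  candidates$scores <- scores
  candidates$best_index <- best
  candidates$margin <- margin
  candidates$margin_tol <- tol
  candidates$ambiguous <- is.na(tol) || margin < tol
  candidates
}

#' Score a particle's candidates in one call
#'
#' Convenience wrapper: enumerate candidates from the icosahedral pose,
#' build the mask library, and score.
#'
#' @param image N x N matrix.
#' @param icos_pose a [pose()] in the asymmetric unit.
#' @param model a [vertex_model()].
#' @param group an [icosahedral_group()].
#' @inheritParams score_candidates
#' @return a scored `candidate_set`.
#' @export
score_particle <- function(image, icos_pose, model,
                           group = icosahedral_group(),
                           scorer = "masked-ncc", margin_factor = 2,
                           reference_projector = NULL) {
  cand <- enumerate_candidates(icos_pose, group)
  lib <- build_mask_library(model, cand)
  if (!is.null(reference_projector)) {
    R <- if (inherits(icos_pose, "pose")) pose_matrix(icos_pose) else icos_pose
    image <- image - project_fourier(reference_projector, R,
                                     lib$sx_px, lib$sy_px)
    return(score_candidates(image, lib, cand, scorer, margin_factor,
                            whiten = FALSE))
  }
  score_candidates(image, lib, cand, scorer, margin_factor)
}

#' Locate the unique vertex by anchoring on the 11 regular vertices
#'
#' For each of the 60 candidates, the score is the mean masked correlation
#' of the 11 non-unique vertex positions against a regular five-fold vertex
#' model; the candidate's hypothesized unique position is excluded. The
#' best candidate designates the unique vertex at the excluded position.
#' Because a candidate's score depends only on which vertex is excluded,
#' the 60 scores are 5-fold degenerate: margins and the ambiguity flag are
#' computed over the 12 distinct vertex hypotheses, and accuracy is
#' meaningful at the vertex level (the 5 in-plane attachments are
#' indistinguishable without an asymmetric vertex feature).
#'
#' @param image N x N numeric matrix.
#' @param icos_pose a [pose()] in the asymmetric unit.
#' @param regular_model a [vertex_model()] built from the regular
#'   five-fold vertex region (`mode = "regular-vertex"`).
#' @param group an [icosahedral_group()].
#' @param margin_factor ambiguity multiplier (default 2).
#' @return a scored `candidate_set` with extra fields `vertex_scores` (the
#'   12 per-vertex correlations) and `best_vertex` (index of the located
#'   unique vertex axis).
#' @export
assign_regular_anchor <- function(image, icos_pose, regular_model,
                                  group = icosahedral_group(),
                                  margin_factor = 2) {
  cand <- enumerate_candidates(icos_pose, group)
  ## one fixed representative group element per vertex (maps axis 1 -> w)
  reps <- match(seq_len(12), group$vertex_of)
  sx <- cand$sx / regular_model$voxel
  sy <- cand$sy / regular_model$voxel
  R0 <- cand$rotations[[1]] %*% t(group$rotations[[1]])  # the input R
  ## whiten about the particle centre: a regular vertex then correlates
  ## weakly positively with the shell template while the carved unique
  ## vertex anticorrelates strongly (the missing-penton deficit)
  image <- whiten_image_about(image, sx, sy)
  c_w <- vapply(seq_len(12), function(w) {
    Rw <- R0 %*% group$rotations[[reps[w]]]
    mj <- project_model(regular_model, Rw, sx, sy, "mask") > 0.5
    if (!any(mj)) return(0)
    pj <- project_model(regular_model, Rw, sx, sy, "density")
    masked_ncc(image, pj, mj)
  }, numeric(1))
  u <- group$vertex_of  # vertex hypothesized unique for candidate j
  scores <- (sum(c_w) - c_w[u]) / 11
  cand <- finalize_candidate_scores(cand, scores, margin_factor,
                                    distinct_groups = u)
  cand$vertex_scores <- c_w
  cand$best_vertex <- u[cand$best_index]
  cand
}

#' The unique vertex axis implied by a candidate index
#'
#' Candidate `j` places the unique vertex (reference axis 1 of the model)
#' at vertex axis `vertex_of[j]` in the icosahedral-pose frame.
#'
#' @param candidate_idx integer candidate indices (1-based).
#' @param group an [icosahedral_group()].
#' @return integer vertex axis indices (1-12).
#' @export
candidate_vertex <- function(candidate_idx, group = icosahedral_group()) {
  group$vertex_of[candidate_idx]
}

## score a whole stack; returns data.frame of assignments
score_stack <- function(stack, icos_poses, model, group, scorer,
                        margin_factor = 2, mode = "vertex",
                        regular_model = NULL, reference = NULL) {
  ref_pj <- if (is.null(reference)) NULL else
    if (is.list(reference) && !inherits(reference, "volume3d")) reference
    else fourier_projector(reference)
  n <- length(stack$ids)
  out <- vector("list", n)
  for (i in seq_len(n)) {
    p <- pose(icos_poses$phi[i], icos_poses$theta[i], icos_poses$psi[i],
              icos_poses$sx[i], icos_poses$sy[i])
    cs <- if (mode == "vertex") {
      score_particle(stack$images[, , i], p, model, group, scorer,
                     margin_factor, reference_projector = ref_pj)
    } else {
      assign_regular_anchor(stack$images[, , i], p, regular_model, group,
                            margin_factor)
    }
    out[[i]] <- data.frame(
      id = stack$ids[i], candidate_idx = cs$best_index,
      score = cs$scores[cs$best_index], margin = cs$margin,
      ambiguous = cs$ambiguous,
      vertex_idx = group$vertex_of[cs$best_index]
    )
  }
  df <- do.call(rbind, out)
  rownames(df) <- NULL
  df
}

#' Iterative refinement of the unique-vertex assignment
#'
#' The core loop: starting from an initial vertex model (a faint feature
#' segmented from the unsymmetrized average map at a very low threshold),
#' every particle's 60 candidates are scored, unsymmetrized half-maps are
#' reconstructed from the current assignments, the vertex model is
#' re-extracted from each half's unmasked map at the current threshold, and
#' the particles are rescored. Assignments are refined independently per
#' even/odd half-set; the final combined map is produced only after both
#' halves converge. Iteration stops when the fraction of particles changing
#' assignment falls below `convergence_frac` or `max_iter` is reached; an
#' agreement that worsens for three consecutive iterations is flagged as
#' divergence (with a warning) rather than silently ignored.
#'
#' @param stack a [particle_stack()].
#' @param icos_poses data.frame of icosahedral poses (columns id, phi,
#'   theta, psi, sx, sy), one row per particle in stack order.
#' @param init_model a [vertex_model()] used for the first scoring pass of
#'   both halves.
#' @param group an [icosahedral_group()].
#' @param max_iter maximum scoring passes per half.
#' @param convergence_frac stop when fewer than this fraction of particles
#'   change assignment.
#' @param scorer `"masked-ncc"` or `"common-lines"`.
#' @param half_angle,threshold_sigma vertex-model re-extraction parameters
#'   (see [vertex_model()]); the radial extent is taken from `init_model`.
#'   Re-extracted models are the residual of each half map against its own
#'   icosahedral average, matching the reference-subtracted scoring.
#' @param reference optional icosahedrally symmetrized [volume3d()]; its
#'   projection at the icosahedral pose is subtracted from every image
#'   before scoring (otherwise the circular average about the particle
#'   centre is).
#' @param model_projection `"fourier"` (accurate, slower) or `"scatter"`
#'   (fast) rendering of the model templates during the iteration.
#' @return object of class `vertex_refine`: `assignments` (data.frame with
#'   id, half, candidate_idx, vertex_idx, score, margin, ambiguous),
#'   `first_pass` (the same table from the first scoring pass, before any
#'   model re-extraction), `map`
#'   (final combined unsymmetrized [volume3d()]), `half_maps` (list a/b),
#'   `log` (per half and iteration: fraction changed, mean score/margin),
#'   `converged`, `diverged`, `models` (final per-half vertex models).
#' @export
refine_unique_vertex <- function(stack, icos_poses, init_model,
                                 group = icosahedral_group(),
                                 max_iter = 10, convergence_frac = 0.02,
                                 scorer = "masked-ncc",
                                 half_angle = init_model$half_angle,
                                 threshold_sigma = 0.5,
                                 reference = NULL,
                                 model_projection = c("fourier", "scatter")) {
  model_projection <- match.arg(model_projection)
  use_fourier <- model_projection == "fourier"

  if (sum(init_model$mask) == 0) stop("initial vertex model is empty")
  ref_pj <- if (is.null(reference)) NULL else fourier_projector(reference)
  split <- split_halves(stack$ids)
  halves <- list(a = match(split$even, stack$ids),
                 b = match(split$odd, stack$ids))
  logs <- list()
  results <- list()
  half_maps <- list()
  models <- list()
  for (h in names(halves)) {
    sel <- halves[[h]]
    sub_stack <- particle_stack(stack$images[, , sel, drop = FALSE],
                                stack$voxel, stack$ids[sel])
    sub_poses <- icos_poses[sel, , drop = FALSE]
    ## per-particle context fixed across iterations: the candidate poses,
    ## the projected cone masks (model-independent geometry) and the
    ## (reference-subtracted or whitened) image
    ctx <- lapply(seq_along(sub_stack$ids), function(i) {
      p <- pose(sub_poses$phi[i], sub_poses$theta[i], sub_poses$psi[i],
                sub_poses$sx[i], sub_poses$sy[i])
      cand <- enumerate_candidates(p, group)
      sxp <- cand$sx / sub_stack$voxel
      syp <- cand$sy / sub_stack$voxel
      masks <- lapply(cand$rotations, function(R) {
        project_model(init_model, R, sxp, syp, "mask") > 0.5
      })
      img <- sub_stack$images[, , i]
      img <- if (is.null(ref_pj)) {
        whiten_image_about(img, sxp, syp)
      } else {
        img - project_fourier(ref_pj, pose_matrix(p), sxp, syp)
      }
      list(cand = cand, masks = masks, image = img, sxp = sxp, syp = syp,
           id = sub_stack$ids[i])
    })
    score_ctx <- function(model) {
      rows <- lapply(ctx, function(cx) {
        projs <- lapply(cx$cand$rotations, function(R) {
          project_model(model, R, cx$sxp, cx$syp, "density",
                        fourier = use_fourier)
        })
        scores <- vapply(seq_along(projs), function(j) {
          masked_ncc(cx$image, projs[[j]], cx$masks[[j]])
        }, numeric(1))
        scores[!is.finite(scores)] <- 0
        cs <- finalize_candidate_scores(cx$cand, scores, 2)
        data.frame(id = cx$id, candidate_idx = cs$best_index,
                   score = cs$scores[cs$best_index], margin = cs$margin,
                   ambiguous = cs$ambiguous,
                   vertex_idx = group$vertex_of[cs$best_index])
      })
      df <- do.call(rbind, rows)
      rownames(df) <- NULL
      df
    }
    model <- init_model
    prev <- NULL
    worse_run <- 0
    prev_frac <- Inf
    converged <- FALSE
    diverged <- FALSE
    first_pass <- NULL
    for (it in seq_len(max_iter)) {
      asg <- if (scorer == "masked-ncc") score_ctx(model) else
        score_stack(sub_stack, sub_poses, model, group, scorer,
                    reference = ref_pj)
      if (it == 1) first_pass <- asg
      frac <- if (is.null(prev)) NA_real_ else
        mean(asg$candidate_idx != prev$candidate_idx)
      logs[[length(logs) + 1]] <- data.frame(
        half = h, iter = it, frac_changed = frac,
        mean_score = mean(asg$score), mean_margin = mean(asg$margin),
        frac_ambiguous = mean(asg$ambiguous)
      )
      map <- backproject_assigned(sub_stack, sub_poses, asg$candidate_idx,
                                  group)
      model <- vertex_model(map, init_model$radial_extent, half_angle,
                            threshold_sigma = threshold_sigma,
                            mode = init_model$mode,
                            background_map = symmetrize_icos(map, group))
      if (!is.na(frac)) {
        if (frac > prev_frac) worse_run <- worse_run + 1 else worse_run <- 0
        prev_frac <- frac
        if (worse_run >= 3) {
          diverged <- TRUE
          warning("assignment agreement decreased for 3 consecutive ",
                  "iterations in half ", h, "; refinement diverging")
          prev <- asg
          break
        }
        if (frac < convergence_frac) {
          prev <- asg
          converged <- TRUE
          break
        }
      }
      prev <- asg
    }
    prev$half <- h
    first_pass$half <- h
    results[[h]] <- prev
    attr(results[[h]], "first_pass") <- first_pass
    half_maps[[h]] <- backproject_assigned(sub_stack, sub_poses,
                                           prev$candidate_idx, group)
    models[[h]] <- model
    attr(results[[h]], "converged") <- converged
    attr(results[[h]], "diverged") <- diverged
  }
  assignments <- do.call(rbind, results)
  assignments <- assignments[order(assignments$id), ]
  rownames(assignments) <- NULL
  first_pass <- rbind(attr(results$a, "first_pass"),
                      attr(results$b, "first_pass"))
  first_pass <- first_pass[order(first_pass$id), ]
  rownames(first_pass) <- NULL
  combined <- volume3d((half_maps$a$data + half_maps$b$data) / 2,
                       stack$voxel)
  structure(list(
    assignments = assignments,
    first_pass = first_pass,
    map = combined,
    half_maps = half_maps,
    log = do.call(rbind, logs),
    converged = attr(results$a, "converged") && attr(results$b, "converged"),
    diverged = attr(results$a, "diverged") || attr(results$b, "diverged"),
    models = models,
    n_particles = length(stack$ids)
  ), class = "vertex_refine")
}

## reconstruct (sym = none) with candidate poses R_icos G_j per particle
backproject_assigned <- function(stack, icos_poses, candidate_idx, group) {
  n <- length(stack$ids)
  poses <- icos_poses
  rots <- vector("list", n)
  for (i in seq_len(n)) {
    R <- euler_to_matrix(poses$phi[i], poses$theta[i], poses$psi[i])
    rots[[i]] <- R %*% group$rotations[[candidate_idx[i]]]
  }
  backproject(stack, list(rotations = rots, sx = poses$sx, sy = poses$sy),
              symmetry = "none")
}

#' @export
print.vertex_refine <- function(x, ...) {
  cat("Unique-vertex refinement\n")
  cat(sprintf("  particles: %d (halves %d/%d)\n", x$n_particles,
              sum(x$assignments$half == "a"), sum(x$assignments$half == "b")))
  cat(sprintf("  %s after %d scoring passes%s\n",
              if (x$converged) "converged" else "stopped",
              max(x$log$iter), if (x$diverged) " (DIVERGED)" else ""))
  cat(sprintf("  ambiguous particles: %.1f%%\n",
              100 * mean(x$assignments$ambiguous)))
  invisible(x)
}

#' @export
summary.vertex_refine <- function(object, truth = NULL, ...) {
  out <- list(
    n_particles = object$n_particles,
    converged = object$converged,
    diverged = object$diverged,
    n_iterations = max(object$log$iter),
    mean_score = mean(object$assignments$score),
    mean_margin = mean(object$assignments$margin),
    frac_ambiguous = mean(object$assignments$ambiguous)
  )
  if (!is.null(truth)) {
    out$candidate_accuracy <- assignment_accuracy(object$assignments, truth)
    m <- merge(object$assignments, truth, by = "id",
               suffixes = c("", ".true"))
    out$vertex_accuracy <-
      mean(candidate_vertex(m$candidate_idx) ==
             candidate_vertex(m$candidate_idx.true))
  }
  structure(out, class = "summary.vertex_refine")
}

#' @export
print.summary.vertex_refine <- function(x, ...) {
  cat("Unique-vertex refinement summary\n")
  for (nm in names(x)) {
    v <- x[[nm]]
    cat(sprintf("  %-20s %s\n", nm,
                if (is.numeric(v)) format(v, digits = 4) else as.character(v)))
  }
  invisible(x)
}

#' @export
plot.vertex_refine <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(op))
  for (h in unique(x$log$half)) {
    lg <- x$log[x$log$half == h, ]
    if (h == unique(x$log$half)[1]) {
      graphics::plot(lg$iter, lg$frac_changed, type = "b", pch = 19,
                     xlab = "iteration", ylab = "fraction changed",
                     main = "assignment convergence",
                     ylim = c(0, max(x$log$frac_changed, na.rm = TRUE)))
    } else {
      graphics::lines(lg$iter, lg$frac_changed, type = "b", pch = 1)
    }
  }
  graphics::hist(x$assignments$margin, breaks = 20,
                 xlab = "score margin", main = "candidate margins")
  graphics::abline(v = mean(x$assignments$margin), lty = 2)
  invisible(x)
}
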