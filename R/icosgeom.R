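## Icosahedral point-group machinery and capsid stoichiometry arithmetic.

the_group_cache <- new.env(parent = emptyenv())

#' The icosahedral proper rotation group
#'
#' Returns the 60 proper rotations of the icosahedral group I in the "222"
#' setting (2-fold axes along the coordinate axes), together with the 12
#' five-fold vertex axes. Vertex axis 1 is the axis with the largest +z
#' component (ties broken by larger y); the unique vertex of every phantom
#' in this package is planted along it. The element order is deterministic:
#' elements are sorted lexicographically on their rounded matrices with the
#' identity first.
#'
#' @return an object of class `icos_group`: a list with `rotations` (list of
#'   60 3x3 matrices), `vertex_axes` (3 x 12 matrix of unit columns),
#'   `convention_tag` (`"I-222/z-vertex1"`), plus lookup tables used by the
#'   symmetry-breaking search: `inverse_index` (index of each element's
#'   inverse) and `vertex_of` (which vertex axis each element sends axis 1
#'   to).
#' @export
icosahedral_group <- function() {
  if (!is.null(the_group_cache$group)) return(the_group_cache$group)
  gr <- (1 + sqrt(5)) / 2
  ## icosahedron vertices in the 222 setting: cyclic permutations of
  ## (0, +-1, +-gr)
  verts <- cbind(
    expand_signs(c(0, 1, gr)),
    expand_signs(c(1, gr, 0)),
    expand_signs(c(gr, 0, 1))
  )
  verts <- verts / sqrt(1 + gr^2)
  ## order: decreasing z, then decreasing y, then decreasing x
  ord <- order(-round(verts[3, ], 9), -round(verts[2, ], 9),
               -round(verts[1, ], 9))
  verts <- verts[, ord, drop = FALSE]

  ## generate the group by closure from a 5-fold and a 2-fold
  gens <- list(rot_axis(verts[, 1], 72), diag(c(-1, -1, 1)))
  elems <- list(diag(3))
  keys <- mat_key(diag(3))
  repeat {
    added <- FALSE
    for (e in elems) {
      for (g in gens) {
        m <- e %*% g
        k <- mat_key(m)
        if (!(k %in% keys)) {
          elems[[length(elems) + 1]] <- m
          keys <- c(keys, k)
          added <- TRUE
        }
      }
    }
    if (!added) break
  }
  stopifnot(length(elems) == 60)
  ## deterministic order: identity first, then lexicographic on rounded key
  keys <- vapply(elems, mat_key, "")
  idkey <- mat_key(diag(3))
  ord <- order(keys != idkey, keys)
  elems <- elems[ord]

  vertex_of <- vapply(elems, function(g) {
    axis_index(verts, g %*% verts[, 1])
  }, integer(1))
  inverse_index <- vapply(elems, function(g) {
    group_lookup(elems, t(g))
  }, integer(1))

  group <- structure(
    list(
      rotations = elems,
      vertex_axes = verts,
      convention_tag = "I-222/z-vertex1",
      inverse_index = inverse_index,
      vertex_of = vertex_of
    ),
    class = "icos_group"
  )
  the_group_cache$group <- group
  group
}

expand_signs <- function(v) {
  nz <- which(v != 0)
  signs <- as.matrix(expand.grid(rep(list(c(1, -1)), length(nz))))
  out <- matrix(v, nrow = 3, ncol = nrow(signs))
  for (i in seq_len(nrow(signs))) out[nz, i] <- v[nz] * signs[i, ]
  out
}

mat_key <- function(m) paste(sprintf("%.9f", round(m, 9) + 0), collapse = ",")

## index of the axis (column of `axes`) matching vector v, tolerance 1e-9
axis_index <- function(axes, v, tol = 1e-6) {
  d <- colSums((axes - as.vector(v))^2)
  i <- which.min(d)
  if (d[i] > tol) stop("vector does not match any vertex axis")
  i
}

## index of the group element closest to M (error if not a member)
group_lookup <- function(rotations, M, tol = 1e-6) {
  d <- vapply(rotations, function(g) sum((g - M)^2), numeric(1))
  i <- which.min(d)
  if (d[i] > tol) stop("matrix is not a member of the group")
  i
}

#' @export
print.icos_group <- function(x, ...) {
  cat("Icosahedral proper rotation group (", x$convention_tag, ")\n", sep = "")
  cat("  60 rotations, 12 five-fold vertex axes\n")
  cat("  vertex axis 1:", paste(sprintf("%.4f", x$vertex_axes[, 1]),
                                collapse = " "), "\n")
  invisible(x)
}

#' Rotation distance modulo the icosahedral group
#'
#' Smallest geodesic distance between `R1` and any icosahedrally equivalent
#' version `R2 %*% G` of `R2`.
#'
#' @param R1,R2 3x3 rotation matrices.
#' @param group an [icosahedral_group()].
#' @return distance in degrees.
#' @export
rotation_distance_icos <- function(R1, R2, group = icosahedral_group()) {
  min(vapply(group$rotations, function(g) rotation_distance(R1, R2 %*% g),
             numeric(1)))
}

## A fixed generic linear functional on rotation matrices used to pick the
## canonical representative of the 60-member orbit {R G}. Generic entries
## make the argmax unique almost everywhere.
W_CANON <- matrix(c(
  0.8147236, 0.9057919, 0.1269868,
  0.9133759, 0.6323593, 0.0975404,
  0.2784982, 0.5468815, 0.9575068
), 3, 3)

#' Canonical icosahedral representative of a rotation
#'
#' Reduces a pose rotation to a canonical member of its orbit
#' `{R %*% G : G in I}` (the icosahedral asymmetric unit used throughout the
#' package). The representative maximizes a fixed generic linear functional
#' of the matrix, which selects a unique member for almost every pose.
#'
#' @param R 3x3 rotation matrix.
#' @param group an [icosahedral_group()].
#' @return list with `R` (canonical rotation), `index` (the group index `j`
#'   such that canonical = `R %*% G_j`), and `candidate_index` (the index
#'   `j*` such that `canonical %*% G_j*` recovers the input `R`).
#' @export
canonical_icos_pose <- function(R, group = icosahedral_group()) {
  s <- vapply(group$rotations, function(g) sum(W_CANON * (R %*% g)),
              numeric(1))
  j <- which.max(s)
  list(R = R %*% group$rotations[[j]], index = j,
       candidate_index = group$inverse_index[j])
}

#' Size of the candidate orbit in the symmetry-relaxation search
#'
#' The number of icosahedrally equivalent orientation choices for a single
#' vertex-anchored asymmetric feature: number of vertex locations times the
#' order of a vertex's rotational stabilizer (12 x 5 = 60).
#'
#' @param n_vertex_axes number of 5-fold vertex axes (12 for I).
#' @param stabilizer_order order of one vertex's stabilizer (5 for I).
#' @return `n_vertex_axes * stabilizer_order`.
#' @export
candidate_orbit_size <- function(n_vertex_axes, stabilizer_order) {
  if (n_vertex_axes <= 0 || stabilizer_order <= 0)
    stop("counts must be positive")
  n_vertex_axes * stabilizer_order
}

#' Capsid stoichiometry after removing the unique vertex
#'
#' Copy-number arithmetic for a capsid whose unique vertex replaces
#' `pentons_removed` pentons and their peripentonal major-capsid-protein
#' (MCP) trimers: the packaging complex displaces the penton (5 monomers)
#' and `peripentonal_trimers_removed_per_penton` MCP trimers (3 monomers
#' each).
#'
#' @param mcp_monomers_total total MCP monomers in the fully icosahedral
#'   shell (720 for a pseudo-T = 25 double jelly-roll capsid).
#' @param penton_monomers_total total penton monomers (60).
#' @param pentons_removed number of vertices converted to unique vertices.
#' @param peripentonal_trimers_removed_per_penton trimers removed around
#'   each converted vertex.
#' @return object of class `capsid_stoichiometry`: list with `mcp_trimers`,
#'   `mcp_monomers`, `penton_monomers`.
#' @export
capsid_counts <- function(mcp_monomers_total, penton_monomers_total,
                          pentons_removed,
                          peripentonal_trimers_removed_per_penton) {
  mcp <- mcp_monomers_total -
    pentons_removed * peripentonal_trimers_removed_per_penton * 3
  pen <- penton_monomers_total - 5 * pentons_removed
  if (mcp < 0 || pen < 0) stop("removals exceed totals")
  structure(
    list(mcp_trimers = mcp / 3, mcp_monomers = mcp, penton_monomers = pen),
    class = "capsid_stoichiometry"
  )
}

#' @export
print.capsid_stoichiometry <- function(x, ...) {
  cat("Capsid stoichiometry:\n")
  cat(sprintf("  MCP monomers:    %d (%g trimers)\n", x$mcp_monomers,
              x$mcp_trimers))
  cat(sprintf("  penton monomers: %d\n", x$penton_monomers))
  invisible(x)
}

#' Double jelly-roll MCP copies from a pseudo-T number
#'
#' A pseudo-T lattice has `60 t` quasi-equivalent jelly-roll positions;
#' the 60 penton positions carry single jelly-roll subunits and each MCP
#' contributes two jelly rolls, so the MCP copy number is `(60 t - 60) / 2`
#' (720 for pseudo-T = 25).
#'
#' @param t pseudo-triangulation number.
#' @return MCP copy count.
#' @export
mcp_copies_from_pseudo_t <- function(t) {
  if (t < 1) stop("t must satisfy 60*t >= 60")
  n <- (60 * t - 60) / 2
  if (n != round(n)) stop("non-integral copy number for t = ", t)
  as.integer(n)
}

#' Total mass of a protein complex
#'
#' Convenience stoichiometric sum `sum(copies * masses)`, e.g. the hexameric
#' transmembrane conduit built from 6 copies each of two small membrane
#' proteins.
#'
#' @param copies integer vector of copy numbers.
#' @param masses numeric vector of per-copy masses (kDa).
#' @return total mass (kDa).
#' @export
complex_mass <- function(copies, masses) {
  if (length(copies) != length(masses)) stop("length mismatch")
  if (any(copies < 0) || any(masses < 0)) stop("negative input")
  sum(copies * masses)
}
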