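## Volume container and MRC/CCP4 + table I/O.

#' Cubic density volume
#'
#' Light container for the map currency of every pipeline stage: a cubic
#' voxel grid of density with a physical voxel size. The physical centre of
#' the grid sits at 0-based voxel index `N %/% 2` on every axis, matching
#' the centred-FFT convention used by the projector and the reconstruction.
#'
#' @param data numeric 3-D array with equal, even dimensions.
#' @param voxel voxel size in Angstrom.
#' @return an object of class `volume3d` with fields `data` and `voxel`.
#' @export
volume3d <- function(data, voxel) {
  d <- dim(data)
  if (length(d) != 3 || length(unique(d)) != 1)
    stop("volume must be a cubic 3-D array")
  if (d[1] %% 2 != 0)
    stop("box size must be even")
  if (!is.numeric(voxel) || length(voxel) != 1 || voxel <= 0)
    stop("voxel size must be a positive scalar (Angstrom)")
  structure(list(data = data, voxel = voxel), class = "volume3d")
}

#' @export
print.volume3d <- function(x, ...) {
  n <- dim(x$data)[1]
  cat(sprintf("volume3d: %d^3 voxels, %.3f A/voxel (%.0f A box)\n",
              n, x$voxel, n * x$voxel))
  cat(sprintf("  density range [%.4g, %.4g], mean %.4g\n",
              min(x$data), max(x$data), mean(x$data)))
  invisible(x)
}

#' @export
dim.volume3d <- function(x) dim(x$data)

as_volume_like <- function(data, template) volume3d(data, template$voxel)

stopifnot_same_grid <- function(a, b) {
  if (!identical(dim(a$data), dim(b$data)))
    stop("grid mismatch: maps have different dimensions")
  if (abs(a$voxel - b$voxel) > 1e-6)
    stop("grid mismatch: maps have different voxel sizes")
}

## ---- MRC 2014 I/O (mode 2, little endian) ----

#' Read a CCP4/MRC density map
#'
#' Supports modes 0 (int8), 1 (int16) and 2 (float32). A permuted axis
#' order (MAPC/MAPR/MAPS) is canonicalized to x-fastest on read. Non-cubic
#' grids are rejected.
#'
#' @param path file path.
#' @return a [volume3d()] with attribute `header` (named list of the fields
#'   read: dimensions, mode, voxel size, origin, axis order).
#' @export
read_map <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr_int <- readBin(con, "integer", n = 256, size = 4, endian = "little")
  seek(con, 0)
  hdr_num <- readBin(con, "numeric", n = 256, size = 4, endian = "little")
  nx <- hdr_int[1]; ny <- hdr_int[2]; nz <- hdr_int[3]
  mode <- hdr_int[4]
  if (is.na(nx) || nx <= 0 || nx > 1e4)
    stop("corrupt MRC header in ", path)
  mx <- hdr_int[8]; my <- hdr_int[9]; mz <- hdr_int[10]
  xlen <- hdr_num[11]
  mapc <- hdr_int[17]; mapr <- hdr_int[18]; maps <- hdr_int[19]
  nsymbt <- hdr_int[24]
  origin <- hdr_num[50:52]
  seek(con, 1024 + nsymbt)
  nvox <- as.numeric(nx) * ny * nz
  dat <- switch(as.character(mode),
    "0" = readBin(con, "integer", n = nvox, size = 1, signed = TRUE),
    "1" = readBin(con, "integer", n = nvox, size = 2, endian = "little"),
    "2" = readBin(con, "numeric", n = nvox, size = 4, endian = "little"),
    stop("unsupported MRC mode ", mode)
  )
  arr <- array(as.numeric(dat), c(nx, ny, nz))
  axes <- c(mapc, mapr, maps)
  if (!identical(sort(axes), 1:3)) stop("corrupt axis order in MRC header")
  if (!identical(axes, 1:3)) {
    arr <- aperm(arr, match(1:3, axes))
  }
  d <- dim(arr)
  if (length(unique(d)) != 1)
    stop("non-cubic grid (", paste(d, collapse = "x"), "); pipeline maps must be cubic")
  voxel <- if (mx > 0 && xlen > 0) xlen / mx else 1
  vol <- volume3d(arr, voxel)
  attr(vol, "header") <- list(
    dims = d, mode = mode, voxel = voxel,
    origin = origin, axis_order = axes
  )
  vol
}

## shared writer for volumes (nz sections) and stacks (nz images)
write_mrc_raw <- function(arr, voxel, path, ispg = 1L, axis_order = 1:3) {
  d <- dim(arr)
  if (!identical(axis_order, 1:3)) {
    ## store with permuted axis semantics (used to build test fixtures)
    arr <- aperm(arr, axis_order)
    d <- dim(arr)
  }
  con <- file(path, "wb")
  on.exit(close(con))
  wi <- function(x) writeBin(as.integer(x), con, size = 4, endian = "little")
  wf <- function(x) writeBin(as.numeric(x), con, size = 4, endian = "little")
  wi(d)                       # nx ny nz
  wi(2)                       # mode 2: float32
  wi(c(0, 0, 0))              # nxstart
  wi(d)                       # mx my mz
  wf(d * voxel)               # cell a b c
  wf(c(90, 90, 90))           # cell angles
  wi(axis_order)              # mapc mapr maps
  wf(c(min(arr), max(arr), mean(arr)))
  wi(ispg)                    # ispg: 1 volume, 0 image stack
  wi(0)                       # nsymbt
  wi(rep(0, 25))              # extra (incl. exttyp)
  wf(c(0, 0, 0))              # origin
  writeChar("MAP ", con, 4, eos = NULL)
  writeBin(as.raw(c(0x44, 0x44, 0x00, 0x00)), con)  # machine stamp (LE)
  wf(stats::sd(as.numeric(arr)))
  wi(0)                       # nlabl
  writeBin(raw(800), con)     # labels
  wf(as.numeric(arr))
  invisible(path)
}

#' Write a CCP4/MRC density map (mode 2)
#'
#' @param volume a [volume3d()].
#' @param path output path.
#' @param axis_order internal MAPC/MAPR/MAPS permutation to record (default
#'   canonical `1:3`; other orders are only useful to exercise the reader).
#' @return the path, invisibly.
#' @export
write_map <- function(volume, path, axis_order = 1:3) {
  write_mrc_raw(volume$data, volume$voxel, path, ispg = 1L,
                axis_order = axis_order)
}

## ---- particle stacks ----

#' Particle image stack
#'
#' @param images numeric array `N x N x n` of projection images.
#' @param voxel pixel size in Angstrom.
#' @param ids integer particle ids (0-based, default `0:(n-1)`).
#' @return object of class `particle_stack`.
#' @export
particle_stack <- function(images, voxel, ids = NULL) {
  d <- dim(images)
  if (length(d) != 3 || d[1] != d[2]) stop("images must be an N x N x n array")
  if (is.null(ids)) ids <- seq_len(d[3]) - 1L
  if (length(ids) != d[3]) stop("ids length must match image count")
  structure(list(images = images, voxel = voxel, ids = as.integer(ids)),
            class = "particle_stack")
}

#' @export
print.particle_stack <- function(x, ...) {
  d <- dim(x$images)
  cat(sprintf("particle_stack: %d images of %dx%d px, %.3f A/px\n",
              d[3], d[1], d[2], x$voxel))
  invisible(x)
}

#' Read / write particle stacks as MRC (.mrcs, mode 2)
#' @param path file path.
#' @rdname stack_io
#' @export
read_stack <- function(path) {
  con <- file(path, "rb")
  hdr_int <- readBin(con, "integer", n = 256, size = 4, endian = "little")
  seek(con, 0)
  hdr_num <- readBin(con, "numeric", n = 256, size = 4, endian = "little")
  close(con)
  nx <- hdr_int[1]; ny <- hdr_int[2]; nz <- hdr_int[3]
  if (hdr_int[4] != 2) stop("stack must be MRC mode 2")
  con <- file(path, "rb")
  on.exit(close(con))
  seek(con, 1024 + hdr_int[24])
  dat <- readBin(con, "numeric", n = as.numeric(nx) * ny * nz, size = 4,
                 endian = "little")
  voxel <- if (hdr_int[8] > 0 && hdr_num[11] > 0) hdr_num[11] / hdr_int[8] else 1
  particle_stack(array(dat, c(nx, ny, nz)), voxel)
}

#' @param stack a [particle_stack()].
#' @rdname stack_io
#' @export
write_stack <- function(stack, path) {
  write_mrc_raw(stack$images, stack$voxel, path, ispg = 0L)
}

## ---- tab-separated tables ----

TABLE_COLUMNS <- list(
  truth = c("id", "phi", "theta", "psi", "sx", "sy", "candidate_idx", "state"),
  poses = c("id", "phi", "theta", "psi", "sx", "sy", "score", "kept"),
  assignments = c("id", "candidate_idx", "score", "margin", "ambiguous")
)

#' Read / write tab-separated metadata tables
#'
#' Plain TSV with a header row; floats are serialized with 9 significant
#' digits. `kind` selects a documented column set (`"truth"`, `"poses"`,
#' `"assignments"`) whose presence is checked; `NULL` skips the check.
#'
#' @param path file path.
#' @param kind optional column-set name to validate against.
#' @return `read_table`: a data.frame.
#' @rdname table_io
#' @export
read_table <- function(path, kind = NULL) {
  df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  if (!is.null(kind)) {
    req <- TABLE_COLUMNS[[kind]]
    missing <- setdiff(req, names(df))
    if (length(missing))
      stop("table ", path, " is missing required column(s): ",
           paste(missing, collapse = ", "))
  }
  df
}

#' @param records a data.frame.
#' @rdname table_io
#' @export
write_table <- function(records, path, kind = NULL) {
  if (!is.null(kind)) {
    req <- TABLE_COLUMNS[[kind]]
    missing <- setdiff(req, names(records))
    if (length(missing))
      stop("records are missing required column(s): ",
           paste(missing, collapse = ", "))
  }
  out <- records
  for (j in seq_along(out)) {
    if (is.double(out[[j]])) out[[j]] <- signif(out[[j]], 9)
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Assignment accuracy against ground truth
#'
#' Joins an assignment table to a ground-truth table on `id` and returns the
#' fraction of particles whose `candidate_idx` matches.
#'
#' @param assignments data.frame with `id`, `candidate_idx`.
#' @param truth data.frame with `id`, `candidate_idx`.
#' @return accuracy in `[0, 1]`.
#' @export
assignment_accuracy <- function(assignments, truth) {
  m <- merge(assignments, truth, by = "id", suffixes = c("", ".true"))
  if (nrow(m) == 0) stop("no overlapping ids")
  mean(m$candidate_idx == m$candidate_idx.true)
}
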