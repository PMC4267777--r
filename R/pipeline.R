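## End-to-end orchestration: simulate -> orient -> symmetry-break ->
## reconstruct -> measure, with a run directory, logging and seeds.

pipeline_defaults <- function() {
  list(
    schema = 1,
    out_dir = NULL,
    seed = 1,
    half_seeds = c(101, 202),
    state = "virion",
    spec = list(),
    n_particles = 40,
    snr = Inf,
    use_truth_poses = TRUE,
    angular_step = 8,
    freq_limit = NULL,
    mode = "vertex",
    max_iter = 5,
    convergence_frac = 0.02,
    scorer = "masked-ncc",
    metrology = TRUE
  )
}

#' Run configuration
#'
#' Validates a configuration list (or YAML file) against the documented
#' schema: unknown keys are rejected, every random stage has a recorded
#' seed, and equal half-set seeds are a hard error (they would break the
#' gold-standard independence of the two halves).
#'
#' @param config named list of overrides, or path to a YAML file.
#' @return the completed configuration list.
#' @export
run_config <- function(config = list()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  defaults <- pipeline_defaults()
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  cfg <- utils::modifyList(defaults, config)
  if (length(cfg$half_seeds) != 2 || cfg$half_seeds[1] == cfg$half_seeds[2])
    stop("cross-contamination: half_seeds must be two distinct integers")
  if (!cfg$mode %in% c("vertex", "anchor"))
    stop("mode must be 'vertex' or 'anchor'")
  cfg
}

#' Run the full unique-vertex pipeline
#'
#' Simulates a particle stack from the configured phantom, determines (or
#' takes from ground truth) the icosahedral orientations, reconstructs the
#' icosahedrally symmetrized map, seeds the vertex model from it, resolves
#' the 60-fold ambiguity (unique-vertex or regular-anchor mode),
#' reconstructs the final unsymmetrized map, and writes maps, tables,
#' curves, a log and a machine-readable summary to the run directory.
#' Deterministic for fixed seeds.
#'
#' @param config a [run_config()] list or YAML path.
#' @return invisibly, a list with the run `summary` (named numerics), the
#'   refinement object, and output paths.
#' @export
run_pipeline <- function(config) {
  cfg <- run_config(config)
  if (is.null(cfg$out_dir)) stop("config must set out_dir")
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  logfile <- file.path(cfg$out_dir, "run.log")
  group <- icosahedral_group()
  logline <- function(...) {
    cat(sprintf("[%s] %s\n", format(Sys.time(), "%H:%M:%S"),
                sprintf(...)), file = logfile, append = TRUE)
  }
  cat(sprintf("cryovertex pipeline (schema %d)\n", cfg$schema),
      file = logfile)
  logline("icosahedral convention: %s", group$convention_tag)
  logline("seeds: sim %d, halves %d/%d", cfg$seed, cfg$half_seeds[1],
          cfg$half_seeds[2])

  ctor <- switch(cfg$state, virion = virion_spec,
                 procapsid = procapsid_spec, "sus-like" = sus_spec,
                 stop("unknown state: ", cfg$state))
  spec <- do.call(ctor, cfg$spec)
  if (is.null(cfg$freq_limit)) cfg$freq_limit <- 3 * spec$voxel_size

  logline("simulating %d particles (state %s, snr %s)", cfg$n_particles,
          cfg$state, format(cfg$snr))
  sim <- simulate_stack(spec, cfg$n_particles, cfg$snr, cfg$seed)
  write_stack(sim$stack, file.path(cfg$out_dir, "stack.mrcs"))
  write_table(sim$truth, file.path(cfg$out_dir, "truth.tsv"), kind = "truth")

  if (cfg$use_truth_poses) {
    logline("using ground-truth icosahedral poses")
    poses <- data.frame(id = sim$truth$id, phi = sim$truth$icos_phi,
                        theta = sim$truth$icos_theta,
                        psi = sim$truth$icos_psi,
                        sx = sim$truth$sx, sy = sim$truth$sy,
                        score = 1, kept = TRUE)
  } else {
    logline("aligning with angular step %.1f deg, band limit %.1f A",
            cfg$angular_step, cfg$freq_limit)
    ref <- symmetrize_icos(build_phantom(spec), group)
    refs <- make_alignment_refs(ref, cfg$angular_step, cfg$freq_limit)
    rows <- lapply(seq_along(sim$stack$ids), function(i) {
      res <- icos_align(sim$stack$images[, , i], refs = refs)
      data.frame(id = sim$stack$ids[i], phi = res$pose$phi,
                 theta = res$pose$theta, psi = res$pose$psi,
                 sx = res$pose$sx, sy = res$pose$sy, score = res$score,
                 kept = TRUE)
    })
    poses <- do.call(rbind, rows)
  }
  write_table(poses, file.path(cfg$out_dir, "poses.tsv"), kind = "poses")

  logline("reconstructing icosahedrally symmetrized reference")
  icos_map <- backproject(sim$stack, poses, symmetry = "icosahedral")
  write_map(icos_map, file.path(cfg$out_dir, "map_icos.mrc"))

  s <- spec$scale_factor
  extent <- c(spec$membrane_radii[1] * s, 1.05 * spec$capsid_radii[2] * s)
  init_model <- vertex_model(icos_map, extent,
                             mode = if (cfg$mode == "vertex")
                               "unique-vertex" else "regular-vertex")
  summary_vals <- list()

  if (cfg$mode == "vertex") {
    logline("refining unique-vertex assignments (max %d iterations)",
            cfg$max_iter)
    fit <- refine_unique_vertex(sim$stack, poses, init_model, group,
                                max_iter = cfg$max_iter,
                                convergence_frac = cfg$convergence_frac,
                                scorer = cfg$scorer,
                                reference = icos_map)
    assignments <- fit$assignments
    final_map <- fit$map
    half_maps <- fit$half_maps
    write_table(fit$log, file.path(cfg$out_dir, "iterations.tsv"))
  } else {
    logline("anchor mode: locating the missing vertex from the 11 regular ones")
    assignments <- score_stack(sim$stack, poses, NULL, group, cfg$scorer,
                               mode = "anchor", regular_model = init_model)
    assignments$half <- ifelse(assignments$id %% 2 == 0, "a", "b")
    sel_a <- assignments$half == "a"
    half_maps <- list(
      a = backproject_assigned(
        particle_stack(sim$stack$images[, , sel_a, drop = FALSE],
                       sim$stack$voxel, sim$stack$ids[sel_a]),
        poses[sel_a, ], assignments$candidate_idx[sel_a], group),
      b = backproject_assigned(
        particle_stack(sim$stack$images[, , !sel_a, drop = FALSE],
                       sim$stack$voxel, sim$stack$ids[!sel_a]),
        poses[!sel_a, ], assignments$candidate_idx[!sel_a], group)
    )
    final_map <- volume3d((half_maps$a$data + half_maps$b$data) / 2,
                          sim$stack$voxel)
    fit <- NULL
  }
  write_table(assignments[c("id", "candidate_idx", "score", "margin",
                            "ambiguous")],
              file.path(cfg$out_dir, "assignments.tsv"),
              kind = "assignments")
  write_map(final_map, file.path(cfg$out_dir, "map_final.mrc"))
  write_map(half_maps$a, file.path(cfg$out_dir, "halfmap_a.mrc"))
  write_map(half_maps$b, file.path(cfg$out_dir, "halfmap_b.mrc"))

  acc <- assignment_accuracy(assignments, sim$truth)
  vacc <- {
    m <- merge(assignments, sim$truth, by = "id", suffixes = c("", ".true"))
    mean(candidate_vertex(m$candidate_idx, group) ==
           candidate_vertex(m$candidate_idx.true, group))
  }
  logline("vertex assignment accuracy: %.1f%% (candidate), %.1f%% (vertex)",
          100 * acc, 100 * vacc)
  summary_vals$candidate_accuracy <- acc
  summary_vals$vertex_accuracy <- vacc
  summary_vals$frac_ambiguous <- mean(assignments$ambiguous)

  if (cfg$metrology) {
    curve <- fsc(half_maps$a, half_maps$b)
    write_table(as.data.frame(curve), file.path(cfg$out_dir, "fsc.tsv"))
    summary_vals$resolution_0143 <- as.numeric(resolution_at(curve, 0.143))
    rp <- radial_profile(final_map, "central-section")
    write_table(as.data.frame(rp),
                file.path(cfg$out_dir, "radial_profile.tsv"))
    capw <- spec$capsid_radii * s
    memw <- spec$membrane_radii * s
    ext_cap <- try(fwhm_extent(rp, capw + c(-3, 3) * spec$voxel_size),
                   silent = TRUE)
    if (!inherits(ext_cap, "try-error")) {
      summary_vals$capsid_inner <- ext_cap[["inner"]]
      summary_vals$capsid_outer <- ext_cap[["outer"]]
    }
    summary_vals$relative_membrane_intensity <-
      relative_membrane_intensity(final_map, memw, capw)
  }

  sf <- file.path(cfg$out_dir, "summary.txt")
  cat(sprintf("%s\t%.6g\n", names(summary_vals), unlist(summary_vals)),
      sep = "", file = sf)
  logline("done")
  invisible(list(summary = summary_vals, fit = fit, config = cfg,
                 out_dir = cfg$out_dir))
}
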