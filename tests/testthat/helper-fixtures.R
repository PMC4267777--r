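## Shared fixtures, built once per test run and cached (several tests need
## the same expensive phantoms / simulated stacks).

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- build()
  .fixtures[[name]]
}

## the study-condition virion phantom (box 96, voxel 5, scale 0.5)
fx_virion_spec <- function() fixture("virion_spec", function() virion_spec())

fx_virion_phantom <- function() {
  fixture("virion_phantom", function() build_phantom(fx_virion_spec()))
}

fx_virion_sym <- function() {
  fixture("virion_sym", function() build_phantom_symmetrized(fx_virion_spec()))
}

## vertex-model radial extent for a spec (membrane inner to 1.05 x capsid
## outer, at the map scale)
model_extent <- function(spec) {
  s <- spec$scale_factor
  c(spec$membrane_radii[1] * s, 1.05 * spec$capsid_radii[2] * s)
}

## the planted-truth vertex model (residual against the symmetrized map)
fx_true_model <- function() {
  fixture("true_model", function() {
    vertex_model(fx_virion_phantom(), model_extent(fx_virion_spec()),
                 background_map = fx_virion_sym())
  })
}

## noiseless study-condition stack, n = 200, seed 1 (criterion runs)
fx_stack200 <- function() {
  fixture("stack200", function() {
    simulate_stack(fx_virion_spec(), 200, snr = Inf, seed = 1)
  })
}

truth_poses <- function(truth) {
  data.frame(id = truth$id, phi = truth$icos_phi, theta = truth$icos_theta,
             psi = truth$icos_psi, sx = truth$sx, sy = truth$sy)
}

## small textured phantom for orientation-determination tests: the
## capsomer texture gives projections a well-determined orientation, which
## a bare two-shell phantom does not have
fx_tex_spec <- function() {
  fixture("tex_spec", function() {
    virion_spec(box_size = 48, voxel_size = 10, capsomer_texture = TRUE)
  })
}

fx_tex_refs <- function() {
  fixture("tex_refs", function() {
    make_alignment_refs(build_phantom_symmetrized(fx_tex_spec()),
                        angular_step = 8, freq_limit = 40)
  })
}

quiet_backproject <- function(...) suppressWarnings(backproject(...))
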