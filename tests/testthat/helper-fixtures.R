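# Shared fixtures, memoized so expensive meshes/simulations build once per run.
.fix <- new.env(parent = emptyenv())

fixture <- function(name, expr) {
  if (is.null(.fix[[name]])) assign(name, force(expr), envir = .fix)
  .fix[[name]]
}

# coarse 20 x 20 x 2.3 mm slab at 1 mm spacing (2400 tets)
slab_coarse <- function() fixture("slab_coarse", {
  pc <- make_sheet_pcd(sheet_spec(20, 20, point_spacing = 1))
  tetrahedralize(extrude_surface(reconstruct_surface(pc), 2.3))
})

slab_coarse_field <- function() fixture("slab_coarse_field",
  template_field(slab_coarse(), 0, 0))

# fine thin strip for conduction-velocity work (0.125 mm in-plane)
cv_strip <- function() fixture("cv_strip", {
  pc <- make_sheet_pcd(sheet_spec(20, 2, point_spacing = 0.125))
  tetrahedralize(extrude_surface(reconstruct_surface(pc), 2.3))
})

cv_strip_field <- function() fixture("cv_strip_field",
  template_field(cv_strip(), 0, 0))

# run a plane wave along +x on a mesh, return the result
run_plane_wave <- function(mesh, field, K = 1, duration = 60, dt = 0.01,
                           output_rate = 2000, stim_x = 1, sigma = NULL) {
  if (is.null(sigma)) sigma <- conductivity_set(K = K)
  tens <- conductivity_tensor(field, sigma)
  prot <- stimulus_protocol(nodes = which(mesh$vertices[, 1] <=
                                            min(mesh$vertices[, 1]) + stim_x))
  simulate_propagation(mesh, tens,
                       simulation_config(dt = dt, duration = duration,
                                         output_rate = output_rate,
                                         stimuli = prot))
}

# macroscopic CV between two x-bands
plane_wave_cv <- function(mesh, res, x_start = c(4.9, 5.1), x_end = c(14.9, 15.1)) {
  v <- mesh$vertices
  st <- which(v[, 1] >= x_start[1] & v[, 1] <= x_start[2])
  en <- which(v[, 1] >= x_end[1] & v[, 1] <= x_end[2])
  measure_cv(v, res$lats, st, en)$cv
}

# healthy 140 ms slab run at 2 kHz output, shared by EGM-morphology tests
slab_healthy_result <- function() fixture("slab_healthy_result",
  run_plane_wave(slab_coarse(), slab_coarse_field(), duration = 140))
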