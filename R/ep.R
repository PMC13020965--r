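#' Resting state of the Courtemanche atrial ionic model
#'
#' The 21-variable state vector (Vm, 15 gates, 5 concentrations) at the
#' published resting conditions.
#'
#' @return Named numeric vector of length 21.
#' @export
courtemanche_initial_state <- function() {
  s <- .cm_initial_state()
  names(s) <- c("Vm", "m", "h", "j", "oa", "oi", "ua", "ui", "xr", "xs",
                "d", "f", "fCa", "u", "v", "w", "Nai", "Ki", "Cai", "Caup", "Carel")
  s
}

#' Right-hand side of the Courtemanche model
#'
#' Time derivatives of all 21 state variables plus the total ionic current.
#' The stimulus is given depolarizing-positive in pA/pF (numerically equal
#' to uA/uF, so `dVm/dt = -Iion + Istim` is in mV/ms); multiplying currents
#' by the surface capacitance Cm (uF/cm^2) converts them to uA/cm^2.
#'
#' @param state numeric vector of length 21 (see
#'   [courtemanche_initial_state()]).
#' @param Istim stimulus current, pA/pF, depolarizing-positive.
#' @return List with `dstate` (length 21, per ms) and `Iion` (pA/pF).
#' @export
courtemanche_rhs <- function(state, Istim = 0) {
  .stop_if(!all(is.finite(state)), "non-finite state")
  out <- .cm_rhs(as.numeric(state), Istim)
  names(out$dstate) <- names(courtemanche_initial_state())
  out
}

#' One explicit ionic step (Rush-Larsen gates, Euler otherwise)
#'
#' Gating variables advance by the exponential Rush-Larsen update (which
#' keeps them in `[0, 1]` unconditionally); Vm and the concentrations advance
#' by forward Euler.
#'
#' @inheritParams courtemanche_rhs
#' @param dt time step, ms.
#' @return Updated state vector.
#' @export
ionic_step <- function(state, dt, Istim = 0) {
  .stop_if(dt <= 0, "dt must be positive")
  .stop_if(!all(is.finite(state)), "non-finite state")
  s <- .cm_step(as.numeric(state), dt, Istim)
  names(s) <- names(courtemanche_initial_state())
  s
}

#' Stimulus protocol
#'
#' A cube-shaped stimulus region with the clinical-protocol defaults: 25
#' pA/pF for 2.5 ms.
#'
#' @param box_min,box_max opposite corners of the cube, mm.  Either may be
#'   omitted if explicit `nodes` are supplied to [simulate_propagation()].
#' @param amplitude stimulus strength, pA/pF (depolarizing).
#' @param duration stimulus duration, ms.
#' @param start onset, ms.
#' @param nodes optional explicit node indices (overrides the box).
#' @return Object of class `stimulus_protocol`.
#' @export
stimulus_protocol <- function(box_min = NULL, box_max = NULL, amplitude = 25,
                              duration = 2.5, start = 0, nodes = NULL) {
  .stop_if(amplitude <= 0 || duration <= 0, "amplitude and duration must be positive")
  if (!is.null(box_min)) {
    .stop_if(any(box_max <= box_min), "stimulus box is empty")
  } else {
    .stop_if(is.null(nodes), "either a box or explicit nodes is required")
  }
  structure(list(box_min = box_min, box_max = box_max, amplitude = amplitude,
                 duration = duration, start = start, nodes = nodes),
            class = "stimulus_protocol")
}

#' Simulation configuration
#'
#' Monodomain constants and run control.  The membrane capacitance is 1
#' uF/cm^2 and the surface-to-volume ratio 1,500 1/cm; production runs use
#' dt = 0.001 ms, while 0.01 ms is adequate for the desk-scale meshes this
#' package targets (the Rush-Larsen gate update stays stable there) and is
#' the default.
#'
#' @param dt time step, ms.
#' @param duration total simulated time, ms.
#' @param output_rate sampling rate of stored Vm/Im histories, Hz.
#' @param chi membrane area per unit tissue volume, 1/cm.
#' @param Cm membrane capacitance, uF/cm^2.
#' @param stimuli list of [stimulus_protocol()] objects.
#' @return Object of class `sim_config`.
#' @export
simulation_config <- function(dt = 0.01, duration = 140, output_rate = 1000,
                              chi = 1500, Cm = 1, stimuli = list()) {
  .stop_if(dt <= 0, "dt must be positive")
  .stop_if(duration <= 0, "duration must be positive")
  if (inherits(stimuli, "stimulus_protocol")) stimuli <- list(stimuli)
  structure(list(dt = dt, duration = duration, output_rate = output_rate,
                 chi = chi, Cm = Cm, stimuli = stimuli), class = "sim_config")
}

#' Assemble lumped mass and stiffness over the conductive subdomain
#'
#' Linear (P1) tetrahedral finite elements on the subdomain-1 elements only:
#' the stiffness matrix is `sum_e vol_e * B_e' sigma_e B_e` with constant
#' per-element gradients, and the lumped (row-sum) nodal volume is
#' `sum_e vol_e / 4` over incident active elements.  Fibrotic (subdomain 2)
#' elements are skipped entirely, which realises the no-flux internal
#' boundaries of percolation fibrosis.  Every stiffness row sums to zero
#' (constant fields are in the null space, i.e. no-flux outer boundaries).
#' Coordinates are converted mm -> cm here so that, with conductivities in
#' mS/cm, `dVm/dt = -(K Vm)_i / (chi Cm Mvol_i)` is in mV/ms.
#'
#' @param mesh a [volume_mesh()].
#' @param tensors per-element conductivity tensors, `3 x 3 x E` array
#'   (mS/cm), e.g. from [conductivity_tensor()].
#' @return List: `K` (sparse `dgCMatrix`, mS), `node_volume` (cm^3, zero for
#'   inactive nodes), `active` (indices of nodes touching subdomain 1),
#'   `h_min` (cm, shortest active edge), `sigma_max` (largest tensor
#'   eigenvalue bound used for the stability estimate).
#' @export
assemble_system <- function(mesh, tensors) {
  stopifnot(inherits(mesh, "lapw_volume_mesh"))
  el <- which(mesh$subdomain == 1L)
  .stop_if(length(el) == 0, "no conductive elements")
  verts <- mesh$vertices / 10   # mm -> cm
  tets <- mesh$tets[el, , drop = FALSE]
  vol <- .tet_volumes(verts, tets)
  .stop_if(any(vol <= 0), "element with non-positive volume")
  ne <- nrow(tets)
  # per-element shape gradients: solve [1 x y z] a = e_k
  # grad row k of B (3 x 4) via explicit inverse of the Jacobian
  p1 <- verts[tets[, 1], , drop = FALSE]
  e1 <- verts[tets[, 2], , drop = FALSE] - p1
  e2 <- verts[tets[, 3], , drop = FALSE] - p1
  e3 <- verts[tets[, 4], , drop = FALSE] - p1
  d6 <- 6 * vol
  # rows of inv(J)' (gradients of barycentric coords 2..4)
  g2 <- cbind(e2[, 2] * e3[, 3] - e2[, 3] * e3[, 2],
              e2[, 3] * e3[, 1] - e2[, 1] * e3[, 3],
              e2[, 1] * e3[, 2] - e2[, 2] * e3[, 1]) / d6
  g3 <- cbind(e3[, 2] * e1[, 3] - e3[, 3] * e1[, 2],
              e3[, 3] * e1[, 1] - e3[, 1] * e1[, 3],
              e3[, 1] * e1[, 2] - e3[, 2] * e1[, 1]) / d6
  g4 <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
              e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
              e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1]) / d6
  g1 <- -(g2 + g3 + g4)
  G <- array(0, c(ne, 4, 3))
  G[, 1, ] <- g1; G[, 2, ] <- g2; G[, 3, ] <- g3; G[, 4, ] <- g4
  sig <- tensors[, , el, drop = FALSE]
  # sigma * grad for each local basis function (matrix() guards ne == 1)
  SG <- array(0, c(ne, 4, 3))
  for (a in 1:3) for (b in 1:3)
    SG[, , a] <- SG[, , a] + matrix(G[, , b], ne) * matrix(sig[a, b, ], ne, 4)
  ii <- jj <- xx <- vector("list", 16)
  q <- 1
  for (a in 1:4) for (b in 1:4) {
    ii[[q]] <- tets[, a]; jj[[q]] <- tets[, b]
    xx[[q]] <- vol * rowSums(matrix(G[, a, ], ne) * matrix(SG[, b, ], ne))
    q <- q + 1
  }
  K <- Matrix::sparseMatrix(i = unlist(ii), j = unlist(jj), x = unlist(xx),
                            dims = rep(nrow(verts), 2))
  nodevol <- tapply_add(as.vector(tets), rep(vol / 4, 4), nrow(verts))
  active <- which(nodevol > 0)
  edges <- rbind(tets[, c(1, 2)], tets[, c(1, 3)], tets[, c(1, 4)],
                 tets[, c(2, 3)], tets[, c(2, 4)], tets[, c(3, 4)])
  h_min <- sqrt(min(rowSums((verts[edges[, 1], , drop = FALSE] -
                             verts[edges[, 2], , drop = FALSE])^2)))
  sigma_max <- max(apply(sig, 3, function(m) sum(abs(m))) / 3) * 3  # bound on spectral radius
  list(K = K, node_volume = nodevol, active = active,
       h_min = h_min, sigma_max = sigma_max)
}

#' Select stimulus nodes from earliest-activating electrodes
#'
#' Electrodes whose recorded LAT is within `window` ms of the earliest LAT
#' are eligible; their nearest tissue nodes (restricted to the cube `box`
#' when given), together with all nodes within one mean edge length of
#' those, form the stimulus set.
#'
#' @param mesh a [volume_mesh()].
#' @param electrodes `n x 3` electrode positions, mm.
#' @param lats recorded LATs, ms (one per electrode).
#' @param window eligibility window, ms (default 2).
#' @param box optional list with `min` and `max` corners (mm).
#' @return Integer vector of stimulus node indices.
#' @export
select_stimulus_nodes <- function(mesh, electrodes, lats, window = 2, box = NULL) {
  stopifnot(inherits(mesh, "lapw_volume_mesh"))
  electrodes <- as.matrix(electrodes)
  ok <- is.finite(lats)
  .stop_if(!any(ok), "no electrode with a finite LAT")
  elig <- which(ok & lats <= min(lats[ok]) + window)
  vv <- mesh$vertices
  near <- unique(.nearest_index(electrodes[elig, , drop = FALSE], vv))
  if (!is.null(box)) {
    inside <- function(i) all(vv[i, ] >= box$min - 1e-9) && all(vv[i, ] <= box$max + 1e-9)
    near <- near[vapply(near, inside, logical(1))]
  }
  .stop_if(length(near) == 0, "stimulus selection is empty (box excludes all candidate nodes)")
  h <- mean(mesh_edge_lengths(mesh))
  d2 <- vapply(seq_len(nrow(vv)), function(i)
    min(colSums((t(vv[near, , drop = FALSE]) - vv[i, ])^2)), 1)
  grown <- which(d2 <= h^2 + 1e-12)
  if (!is.null(box)) grown <- grown[vapply(grown, function(i)
    all(vv[i, ] >= box$min - 1e-9) && all(vv[i, ] <= box$max + 1e-9), logical(1))]
  sort(unique(c(near, grown)))
}

#' Solve the monodomain equations on a tagged mesh
#'
#' Operator-split explicit integration: Rush-Larsen/Euler ionic update plus
#' explicit diffusion with the lumped mass.  Membrane current histories
#' (`Im`, uA/cm^2) are stored for electrogram forward computation, and node
#' LATs are taken at the minimum temporal derivative of the stored Vm
#' history (the same convention the feature extractor applies to traces).
#' Before starting, the explicit-diffusion stability bound
#' `dt <= 0.9 h_min^2 chi Cm / (6 sigma_max)` is enforced.
#'
#' @param mesh a [volume_mesh()] (mm; fibrotic elements tagged subdomain 2).
#' @param tensors `3 x 3 x E` conductivity tensors, mS/cm.
#' @param config a [simulation_config()].
#' @param ionic set `FALSE` to disable membrane currents (pure diffusion, for
#'   conservation checks).
#' @param state optional initial 21 x V state matrix (defaults to the
#'   resting state everywhere).
#' @return Object of class `lapw_sim_result`: `vm` and `im` node-by-time
#'   matrices (inactive nodes `NA`), `times` (ms), `lats` (ms, `NA` where
#'   undefined), `active`, `node_volume` (cm^3), `config`, `stim_nodes`.
#' @export
simulate_propagation <- function(mesh, tensors, config, ionic = TRUE, state = NULL) {
  stopifnot(inherits(mesh, "lapw_volume_mesh"), inherits(config, "sim_config"))
  sys <- assemble_system(mesh, tensors)
  dt_max <- 0.9 * sys$h_min^2 * config$chi * config$Cm / (6 * sys$sigma_max)
  .stop_if(config$dt > dt_max,
           "dt = %g ms violates the explicit stability bound %.4g ms for this mesh",
           config$dt, dt_max)
  n <- nrow(mesh$vertices)
  out_int <- 1000 / config$output_rate          # ms between stored samples
  out_every <- round(out_int / config$dt)
  .stop_if(abs(out_every * config$dt - out_int) > 1e-9,
           "output interval must be an integer multiple of dt")
  n_steps <- round(config$duration / config$dt)
  n_steps <- (n_steps %/% out_every) * out_every
  if (is.null(state)) state <- matrix(courtemanche_initial_state(), 21, n)
  # stimulus protocols -> node sets
  stim_nodes <- list(); amp <- start <- dur <- numeric(0)
  for (p in config$stimuli) {
    nodes <- p$nodes
    if (is.null(nodes)) {
      vv <- mesh$vertices
      nodes <- which(vv[, 1] >= p$box_min[1] & vv[, 1] <= p$box_max[1] &
                     vv[, 2] >= p$box_min[2] & vv[, 2] <= p$box_max[2] &
                     vv[, 3] >= p$box_min[3] & vv[, 3] <= p$box_max[3])
    }
    nodes <- intersect(nodes, sys$active)
    .stop_if(length(nodes) == 0, "a stimulus protocol selects no active nodes")
    stim_nodes[[length(stim_nodes) + 1]] <- as.integer(nodes - 1L)
    amp <- c(amp, p$amplitude); start <- c(start, p$start); dur <- c(dur, p$duration)
  }
  Kc <- methods::as(methods::as(sys$K, "generalMatrix"), "CsparseMatrix")
  inv_m <- numeric(n)
  inv_m[sys$active] <- 1 / (config$chi * config$Cm * sys$node_volume[sys$active])
  res <- .monodomain_run(state, Kc@p, Kc@i, Kc@x, inv_m,
                         as.integer(sys$active - 1L), stim_nodes, amp, start, dur,
                         config$dt, as.integer(n_steps), as.integer(out_every),
                         config$Cm, isTRUE(ionic))
  lats <- rep(NA_real_, n)
  if (ionic && length(res$times) >= 3) {
    lats[sys$active] <- apply(res$vm[sys$active, , drop = FALSE], 1, function(v) {
      if (max(v) < -40) return(NA_real_)   # never activated (subthreshold only)
      d <- .central_diff(v, res$times)
      res$times[which.min(d)]
    })
  }
  structure(list(vm = res$vm, im = res$im, times = res$times, lats = lats,
                 active = sys$active, node_volume = sys$node_volume,
                 state = res$state, config = config,
                 stim_nodes = lapply(stim_nodes, function(i) i + 1L)),
            class = "lapw_sim_result")
}

#' @export
print.lapw_sim_result <- function(x, ...) {
  cat(sprintf("Monodomain result: %d active nodes, %d samples over %.6g ms; %d/%d nodes activated\n",
              length(x$active), length(x$times), max(x$times),
              sum(is.finite(x$lats)), length(x$active)))
  invisible(x)
}

.central_diff <- function(v, t) {
  n <- length(v)
  d <- numeric(n)
  d[2:(n - 1)] <- (v[3:n] - v[1:(n - 2)]) / (t[3:n] - t[1:(n - 2)])
  d[1] <- (v[2] - v[1]) / (t[2] - t[1])
  d[n] <- (v[n] - v[n - 1]) / (t[n] - t[n - 1])
  d
}

#' Integrate a single isolated cell
#'
#' Convenience wrapper running the same Rush-Larsen/Euler scheme with no
#' diffusion, for action-potential oracles and restitution checks.
#'
#' @param duration ms.
#' @param dt time step, ms.
#' @param stim_amplitude pA/pF (depolarizing-positive).
#' @param stim_start,stim_duration ms.
#' @param output_rate Hz.
#' @param state optional initial state (length 21).
#' @return List `time` (ms), `vm` (mV), `state` (final).
#' @export
simulate_cell <- function(duration = 1000, dt = 0.005, stim_amplitude = 0,
                          stim_start = 0, stim_duration = 2.5,
                          output_rate = 2000, state = NULL) {
  if (is.null(state)) state <- courtemanche_initial_state()
  out_every <- round(1000 / output_rate / dt)
  n_steps <- (round(duration / dt) %/% out_every) * out_every
  stim <- if (stim_amplitude > 0) list(0L) else list()
  res <- .monodomain_run(matrix(state, 21, 1), c(0L, 0L), integer(0), numeric(0),
                         0, 0L, stim,
                         if (stim_amplitude > 0) stim_amplitude else numeric(0),
                         if (stim_amplitude > 0) stim_start else numeric(0),
                         if (stim_amplitude > 0) stim_duration else numeric(0),
                         dt, as.integer(n_steps), as.integer(out_every), 1, TRUE)
  list(time = res$times, vm = as.numeric(res$vm[1, ]), state = res$state[, 1])
}

#' Action potential duration at a repolarization fraction
#'
#' @param time,vm trace from [simulate_cell()].
#' @param frac repolarization fraction (0.9 gives APD90).
#' @return Duration in ms from maximum upstroke to the crossing, or `NA` if
#'   repolarization is not reached.
#' @export
apd <- function(time, vm, frac = 0.9) {
  dv <- .central_diff(vm, time)
  i_up <- which.max(dv)
  v_rest <- vm[1]
  v_peak <- max(vm[i_up:length(vm)])
  v_target <- v_peak - frac * (v_peak - v_rest)
  after <- seq(which.max(vm), length(vm))
  cross <- after[which(vm[after] <= v_target)[1]]
  if (is.na(cross)) return(NA_real_)
  time[cross] - time[i_up]
}
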