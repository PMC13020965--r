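#' Specification of a synthetic atrial-sheet point cloud
#'
#' Describes a curved rectangular sheet sampled on a regular grid, emulating
#' the roughly 1 mm spaced point clouds that electroanatomical mapping
#' exports for the left atrial posterior wall.
#'
#' @param extent_x,extent_y sheet extents, mm.
#' @param curvature_radius cylinder radius, mm (`Inf` gives a flat sheet);
#'   the sheet is bent around an axis parallel to y.
#' @param point_spacing target mean nearest-neighbour distance, mm.
#' @param positional_noise_sd isotropic Gaussian positional noise, mm.
#' @param seed integer RNG seed.
#' @return Object of class `sheet_spec`.
#' @export
sheet_spec <- function(extent_x = 40, extent_y = 40, curvature_radius = Inf,
                       point_spacing = 1, positional_noise_sd = 0, seed = 1) {
  .stop_if(extent_x <= 0 || extent_y <= 0, "extents must be positive")
  .stop_if(point_spacing <= 0, "point_spacing must be positive")
  .stop_if(positional_noise_sd < 0, "positional_noise_sd must be >= 0")
  structure(list(extent_x = extent_x, extent_y = extent_y,
                 curvature_radius = curvature_radius,
                 point_spacing = point_spacing,
                 positional_noise_sd = positional_noise_sd,
                 seed = as.integer(seed)), class = "sheet_spec")
}

#' Generate a sheet-like point cloud
#'
#' Points are laid out on a regular grid with the requested spacing, bent
#' around a cylinder of the requested radius (x becomes arc length, so all
#' noiseless points lie exactly on the cylinder), and perturbed by optional
#' Gaussian noise.  Deterministic for a fixed seed.
#'
#' @param spec a [sheet_spec()].
#' @return A [point_cloud()].
#' @export
make_sheet_pcd <- function(spec) {
  stopifnot(inherits(spec, "sheet_spec"))
  xs <- seq(0, spec$extent_x, by = spec$point_spacing)
  ys <- seq(0, spec$extent_y, by = spec$point_spacing)
  g <- as.matrix(expand.grid(x = xs, y = ys))
  if (is.finite(spec$curvature_radius)) {
    R <- spec$curvature_radius
    cx <- spec$extent_x / 2
    phi <- (g[, 1] - cx) / R       # arc length -> angle
    pts <- cbind(cx + R * sin(phi), g[, 2], R * (1 - cos(phi)))
  } else {
    pts <- cbind(g, 0)
  }
  if (spec$positional_noise_sd > 0) {
    pts <- pts + .with_seed(spec$seed,
      matrix(rnorm(length(pts), sd = spec$positional_noise_sd), ncol = 3))
  }
  colnames(pts) <- c("x", "y", "z")
  point_cloud(pts)
}

#' Place a virtual electrode grid above a surface
#'
#' A regular `grid_spacing` raster over the surface's principal plane; each
#' raster node snaps to its nearest surface vertex and is offset `standoff`
#' mm along that vertex's outward normal, putting the electrode in the blood
#' pool just off the tissue.
#'
#' @param surface a [surface_mesh()].
#' @param grid_spacing electrode pitch, mm.
#' @param standoff distance from tissue along the outward normal, mm (> 0).
#' @return `n x 3` matrix of electrode positions (mm), with attribute
#'   `vertex` giving the supporting surface vertex of each electrode.
#' @export
make_electrode_grid <- function(surface, grid_spacing, standoff) {
  stopifnot(inherits(surface, "lapw_surface"))
  .stop_if(standoff <= 0, "electrodes must sit off-tissue: standoff must be > 0")
  fr <- .pca_frame(surface$vertices)
  loc <- sweep(surface$vertices, 2, fr$center) %*% fr$basis
  .stop_if(grid_spacing > diff(range(loc[, 1])) || grid_spacing > diff(range(loc[, 2])),
           "grid_spacing larger than the surface extent; no electrodes")
  u <- seq(min(loc[, 1]), max(loc[, 1]), by = grid_spacing)
  w <- seq(min(loc[, 2]), max(loc[, 2]), by = grid_spacing)
  raster <- as.matrix(expand.grid(u, w))
  near <- .nearest_index(cbind(raster, 0), loc)
  pos <- surface$vertices[near, , drop = FALSE] +
    standoff * surface$vertex_normals[near, , drop = FALSE]
  colnames(pos) <- c("x", "y", "z")
  attr(pos, "vertex") <- near
  pos
}

#' Specification of pseudo-recorded electrograms
#'
#' Statistical model for stand-in "recorded" unipolar electrograms: a planar
#' wave at a fixed conduction velocity assigns local activation times,
#' amplitudes vary log-linearly around a mean, and optional fractionation
#' inserts extra deflections.  Emulates 1 kHz clinical unipolar recordings
#' truncated to the first 140 ms of depolarization.
#'
#' @param cv planar-wave conduction velocity, cm/s.
#' @param amplitude_mean,amplitude_sd peak-to-peak amplitude distribution, mV
#'   (normal, truncated to stay positive).
#' @param fractionation_probability probability that a trace carries extra
#'   deflections.
#' @param extra_deflection_count_range integer range `c(lo, hi)` of extra
#'   deflections when fractionated.
#' @param jitter_sd Gaussian LAT jitter, ms.
#' @param sample_rate Hz.
#' @param duration trace length, ms.
#' @param template_width width parameter of the biphasic template, ms.
#' @param seed integer RNG seed.
#' @return Object of class `pseudo_recording_spec`.
#' @export
pseudo_recording_spec <- function(cv = 70, amplitude_mean = 1.5, amplitude_sd = 0.5,
                                  fractionation_probability = 0,
                                  extra_deflection_count_range = c(1, 3),
                                  jitter_sd = 0, sample_rate = 1000,
                                  duration = 140, template_width = 4, seed = 1) {
  .stop_if(cv <= 0, "cv must be positive")
  .stop_if(sample_rate <= 0, "sample_rate must be positive")
  .stop_if(fractionation_probability < 0 || fractionation_probability > 1,
           "fractionation_probability must be in [0, 1]")
  structure(list(cv = cv, amplitude_mean = amplitude_mean,
                 amplitude_sd = amplitude_sd,
                 fractionation_probability = fractionation_probability,
                 extra_deflection_count_range = as.integer(extra_deflection_count_range),
                 jitter_sd = jitter_sd, sample_rate = sample_rate,
                 duration = duration, template_width = template_width,
                 seed = as.integer(seed)), class = "pseudo_recording_spec")
}

# biphasic (RS) unipolar template: derivative of a Gaussian, positive lobe
# then negative lobe, steepest downslope exactly at `center`; scaled to unit
# peak-to-peak
.egm_template <- function(time, center, width) {
  u <- (time - center) / width
  y <- -u * exp(-u^2 / 2)
  y / (2 * exp(-0.5))     # lobes at u = -/+1 have height exp(-1/2)
}

# single-lobe bump used for fractionation: adds exactly one deflection
.egm_bump <- function(time, center, width) {
  exp(-((time - center) / width)^2 / 2)
}

#' Generate a pseudo-recorded electrogram set
#'
#' Per electrode, the local activation time is distance from the stimulus
#' edge (minimum-x side) divided by the conduction velocity, plus jitter; the
#' waveform is the biphasic template scaled to a drawn amplitude; with the
#' configured probability, fractionation bumps (each contributing one extra
#' deflection) follow the main complex.  Deterministic for a fixed seed.
#'
#' @param electrodes `n x 3` electrode positions (mm).
#' @param spec a [pseudo_recording_spec()].
#' @param lat_offset baseline latency added to every trace, ms.
#' @return An [egm_set()] with provenance `"recorded"` and attribute
#'   `construction` (the true LATs, amplitudes and deflection counts).
#' @export
make_recorded_egm_set <- function(electrodes, spec, lat_offset = 10) {
  stopifnot(inherits(spec, "pseudo_recording_spec"))
  electrodes <- as.matrix(electrodes)
  .stop_if(nrow(electrodes) < 1, "need at least one electrode")
  n <- nrow(electrodes)
  dx_mm <- electrodes[, 1] - min(electrodes[, 1])
  lat <- lat_offset + (dx_mm / 10) / spec$cv * 1000   # mm -> cm -> ms
  dt <- 1000 / spec$sample_rate
  time <- seq(0, spec$duration - dt, by = dt)
  w <- spec$template_width
  draws <- .with_seed(spec$seed, {
    jit <- if (spec$jitter_sd > 0) rnorm(n, sd = spec$jitter_sd) else numeric(n)
    amp <- rnorm(n, spec$amplitude_mean, spec$amplitude_sd)
    frac <- runif(n) < spec$fractionation_probability
    rng <- spec$extra_deflection_count_range
    vals <- rng[1]:rng[2]    # index to dodge sample()'s scalar expansion
    k <- ifelse(frac, vals[sample.int(length(vals), n, replace = TRUE)], 0L)
    list(jit = jit, amp = pmax(amp, 0.05), k = k)
  })
  lat <- lat + draws$jit
  .stop_if(max(lat) + 4 * w > spec$duration,
           "duration %.0f ms too short for latest activation %.1f ms",
           spec$duration, max(lat))
  phi <- matrix(0, length(time), n)
  count <- integer(n)
  for (i in seq_len(n)) {
    y <- draws$amp[i] * .egm_template(time, lat[i], w)
    count[i] <- 2L
    if (draws$k[i] > 0) {
      for (j in seq_len(draws$k[i])) {
        ctr <- lat[i] + 3 * w + j * 3 * w
        if (ctr + 2 * w > spec$duration) break
        y <- y + (-1)^(j + 1) * 0.3 * draws$amp[i] * .egm_bump(time, ctr, w / 1.5)
        count[i] <- count[i] + 1L
      }
    }
    phi[, i] <- y
  }
  out <- egm_set(time, phi, electrodes, provenance = "recorded",
                 sample_rate = spec$sample_rate)
  attr(out, "construction") <- list(lat = lat, amplitude = draws$amp,
                                    deflection_count = count)
  out
}
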