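#' Rule-based transmural fiber field
#'
#' Assigns each element an orthonormal right-handed triad (f, s, n): n is the
#' local transmural direction (gradient of the transmural coordinate the
#' extrusion records), and the in-plane fiber angle rotates linearly from
#' `theta_endo` at the endocardial base to `theta_epi` at the epicardial
#' top, the slight transmural variation atrial posterior-wall bundles show.
#' Angles are measured from the projection of the global x axis onto the
#' local tangent plane.
#'
#' @param mesh a [volume_mesh()] carrying a per-vertex `transmural` field.
#' @param theta_endo,theta_epi fiber angles at the base/top, degrees
#'   (defaults -60 / +60).
#' @return Object of class `lapw_fiber_field`: matrices `f`, `s`, `n`
#'   (`E x 3`) and the per-element transmural depth `depth`.
#' @export
template_field <- function(mesh, theta_endo = -60, theta_epi = 60) {
  stopifnot(inherits(mesh, "lapw_volume_mesh"))
  tm <- mesh$transmural
  .stop_if(is.null(tm) || diff(range(tm)) < 1e-9,
           "mesh has no transmural structure (missing or constant transmural coordinate)")
  verts <- mesh$vertices; tets <- mesh$tets
  ne <- nrow(tets)
  # element-wise P1 gradient of the transmural coordinate = local n direction
  p1 <- verts[tets[, 1], , drop = FALSE]
  e1 <- verts[tets[, 2], , drop = FALSE] - p1
  e2 <- verts[tets[, 3], , drop = FALSE] - p1
  e3 <- verts[tets[, 4], , drop = FALSE] - p1
  d1 <- tm[tets[, 2]] - tm[tets[, 1]]
  d2 <- tm[tets[, 3]] - tm[tets[, 1]]
  d3 <- tm[tets[, 4]] - tm[tets[, 1]]
  nvec <- matrix(0, ne, 3)
  for (i in seq_len(ne)) {
    J <- rbind(e1[i, ], e2[i, ], e3[i, ])
    nvec[i, ] <- solve(J, c(d1[i], d2[i], d3[i]))
  }
  nvec <- nvec / sqrt(rowSums(nvec^2))
  # reference in-plane direction: global x projected on the tangent plane
  ref <- cbind(1 - nvec[, 1]^2, -nvec[, 1] * nvec[, 2], -nvec[, 1] * nvec[, 3])
  deg <- rowSums(ref^2) < 1e-12
  if (any(deg))  # n parallel to x: fall back to global y
    ref[deg, ] <- cbind(-nvec[deg, 2] * nvec[deg, 1],
                        1 - nvec[deg, 2]^2, -nvec[deg, 2] * nvec[deg, 3])
  a1 <- ref / sqrt(rowSums(ref^2))
  a2 <- .cross3(nvec, a1)
  depth <- (tm[tets[, 1]] + tm[tets[, 2]] + tm[tets[, 3]] + tm[tets[, 4]]) / 4
  th <- (theta_endo + depth * (theta_epi - theta_endo)) * pi / 180
  f <- a1 * cos(th) + a2 * sin(th)
  s <- .cross3(nvec, f)
  structure(list(f = f, s = s, n = nvec, depth = depth),
            class = "lapw_fiber_field")
}

.cross3 <- function(a, b) {
  cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
        a[, 3] * b[, 1] - a[, 1] * b[, 3],
        a[, 1] * b[, 2] - a[, 2] * b[, 1])
}

#' @export
print.lapw_fiber_field <- function(x, ...) {
  cat(sprintf("Fiber field: %d element triads\n", nrow(x$f)))
  invisible(x)
}

#' Map a template fiber field onto a target mesh
#'
#' Atlas-style mapping by translation and per-axis scaling only: the
#' template's element centroids are aligned to the target's bounding box and
#' centroid, then each target element inherits the triad of its nearest
#' aligned template element.  Triads are re-orthonormalized afterwards.
#'
#' @param template_mesh,template_field the atlas mesh and its field.
#' @param target_mesh the patient/target [volume_mesh()].
#' @return An `lapw_fiber_field` on the target mesh.
#' @export
map_fibers <- function(template_mesh, template_field, target_mesh) {
  stopifnot(inherits(template_field, "lapw_fiber_field"))
  src <- mesh_centroids(template_mesh)
  dst <- mesh_centroids(target_mesh)
  rs <- apply(src, 2, range); rd <- apply(dst, 2, range)
  ext_s <- rs[2, ] - rs[1, ]; ext_d <- rd[2, ] - rd[1, ]
  .stop_if(any(ext_s < 1e-9) || any(ext_d < 1e-9),
           "degenerate bounding box (zero extent on an axis)")
  scale <- ext_d / ext_s
  aligned <- sweep(sweep(sweep(src, 2, colMeans(src)), 2, scale, `*`),
                   2, colMeans(dst), `+`)
  idx <- .nearest_index(dst, aligned)
  orthonormalize_triads(template_field$f[idx, , drop = FALSE],
                        template_field$s[idx, , drop = FALSE],
                        depth = template_field$depth[idx])
}

#' Re-orthonormalize fiber triads
#'
#' Gram-Schmidt on (f, s); n is recomputed as f x s so the triad is
#' right-handed.
#'
#' @param f,s `E x 3` direction matrices.
#' @param depth optional transmural depths to carry along.
#' @return An `lapw_fiber_field`.
#' @export
orthonormalize_triads <- function(f, s, depth = NULL) {
  f <- f / sqrt(rowSums(f^2))
  s <- s - f * rowSums(s * f)
  s <- s / sqrt(rowSums(s^2))
  structure(list(f = f, s = s, n = .cross3(f, s), depth = depth),
            class = "lapw_fiber_field")
}

#' Monodomain conductivity from bidomain compartment values
#'
#' `sigma_i sigma_e / (sigma_i + sigma_e)` - half the harmonic mean of the
#' intra- and extracellular conductivities along one direction.
#'
#' @param sigma_i,sigma_e intracellular / extracellular conductivity, mS/cm.
#' @return Monodomain conductivity, mS/cm.
#' @export
monodomain_sigma <- function(sigma_i, sigma_e) {
  .stop_if(any(sigma_i <= 0) || any(sigma_e <= 0), "conductivities must be positive")
  sigma_i * sigma_e / (sigma_i + sigma_e)
}

#' Conductivity set
#'
#' Bidomain compartment conductivities with the atrial defaults (fiber
#' direction 1.74 / 6.25 mS/cm intra/extracellular; sheet and sheet-normal
#' 0.193 / 2.36 mS/cm), the derived monodomain values, the blood-bath
#' conductivity used for electrogram forward computation, and the scalar
#' calibration factor `K` that [calibrate_conductivity()] adjusts.
#'
#' @param sigma_li,sigma_le longitudinal intra/extracellular, mS/cm.
#' @param sigma_ti,sigma_te transverse intra/extracellular, mS/cm.
#' @param sigma_b blood bath conductivity, mS/cm.
#' @param K dimensionless scale applied to all four compartment values
#'   before the monodomain reduction.
#' @return Object of class `lapw_conductivity` with fields `sigma_l`,
#'   `sigma_t` (monodomain, mS/cm) among the inputs.
#' @export
conductivity_set <- function(sigma_li = 1.74, sigma_le = 6.25,
                             sigma_ti = 0.193, sigma_te = 2.36,
                             sigma_b = 6.67, K = 1) {
  .stop_if(K <= 0, "K must be positive")
  li <- K * sigma_li; le <- K * sigma_le
  ti <- K * sigma_ti; te <- K * sigma_te
  structure(list(sigma_li = li, sigma_le = le, sigma_ti = ti, sigma_te = te,
                 sigma_l = monodomain_sigma(li, le),
                 sigma_t = monodomain_sigma(ti, te),
                 sigma_b = sigma_b, K = K,
                 base = c(sigma_li, sigma_le, sigma_ti, sigma_te)),
            class = "lapw_conductivity")
}

#' @export
print.lapw_conductivity <- function(x, ...) {
  cat(sprintf("Conductivities (mS/cm): sigma_l %.4f, sigma_t %.4f (K = %.3f), blood %.3g\n",
              x$sigma_l, x$sigma_t, x$K, x$sigma_b))
  invisible(x)
}

#' Per-element orthotropic conductivity tensors
#'
#' `sigma_l f f' + sigma_t (I - f f')`: transversely isotropic about the
#' fiber axis (the sheet and sheet-normal directions share `sigma_t`), so
#' each tensor has eigenvalues `sigma_l, sigma_t, sigma_t`.
#'
#' @param field an `lapw_fiber_field`.
#' @param sigma an `lapw_conductivity`.
#' @return Array `3 x 3 x E`, mS/cm.
#' @export
conductivity_tensor <- function(field, sigma) {
  stopifnot(inherits(field, "lapw_fiber_field"), inherits(sigma, "lapw_conductivity"))
  .stop_if(is.null(sigma$sigma_l) || is.null(sigma$sigma_t), "unset conductivities")
  f <- field$f
  ne <- nrow(f)
  out <- array(0, c(3, 3, ne))
  for (a in 1:3) for (b in 1:3)
    out[a, b, ] <- (sigma$sigma_l - sigma$sigma_t) * f[, a] * f[, b] +
      if (a == b) sigma$sigma_t else 0
  out
}

#' Macroscopic conduction velocity from an activation map
#'
#' Straight-line distance between the centroids of a start and an end point
#' set, divided by the difference of their mean activation times.
#'
#' @param points `N x 3` node coordinates, mm.
#' @param lats per-node activation times, ms.
#' @param start_idx,end_idx index sets near the beginning / end of
#'   propagation.
#' @return Object of class `cv_measurement` with `cv` (cm/s), the centroid
#'   distance (mm) and the LAT means.
#' @export
measure_cv <- function(points, lats, start_idx, end_idx) {
  .stop_if(length(start_idx) == 0 || length(end_idx) == 0, "empty point set")
  .stop_if(!all(is.finite(lats[c(start_idx, end_idx)])),
           "all measurement nodes must be activated (finite LAT)")
  c0 <- colMeans(points[start_idx, , drop = FALSE])
  c1 <- colMeans(points[end_idx, , drop = FALSE])
  dist_mm <- sqrt(sum((c1 - c0)^2))
  .stop_if(dist_mm < 1e-9, "start and end sets coincide")
  dt_ms <- mean(lats[end_idx]) - mean(lats[start_idx])
  .stop_if(dt_ms <= 0, "end set activates no later than start set")
  structure(list(cv = (dist_mm / 10) / dt_ms * 1000, distance_mm = dist_mm,
                 lat_start = mean(lats[start_idx]), lat_end = mean(lats[end_idx])),
            class = "cv_measurement")
}

#' @export
print.cv_measurement <- function(x, ...) {
  cat(sprintf("CV %.1f cm/s over %.1f mm (%.2f -> %.2f ms)\n",
              x$cv, x$distance_mm, x$lat_start, x$lat_end))
  invisible(x)
}

#' Calibrate conductivities to a target conduction velocity
#'
#' Iteratively rescales all four compartment conductivities by a common
#' factor K until the simulated macroscopic CV matches the target.  Because
#' plane-wave CV scales with the square root of the monodomain conductivity,
#' the update `K <- K (cv_target / cv_sim)^2` converges in very few
#' iterations; the convergence test itself uses only the simulated CV, so
#' the final answer does not depend on the update rule.
#'
#' @param run_cv function taking an `lapw_conductivity` and returning the
#'   simulated CV in cm/s (typically a closure around a slab simulation).
#' @param sigma starting [conductivity_set()].
#' @param cv_target target CV, cm/s.
#' @param rel_tol relative tolerance on CV (default 0.05).
#' @param max_iter iteration cap.
#' @return The calibrated `lapw_conductivity` with attributes `cv` (achieved)
#'   and `iterations`.
#' @export
calibrate_conductivity <- function(run_cv, sigma, cv_target, rel_tol = 0.05,
                                   max_iter = 8) {
  .stop_if(cv_target <= 0, "cv_target must be positive")
  K <- sigma$K
  cv <- run_cv(sigma)
  it <- 0
  while (abs(cv - cv_target) / cv_target > rel_tol) {
    it <- it + 1
    .stop_if(it > max_iter,
             "calibration did not converge in %d iterations (last CV %.1f cm/s, target %.1f)",
             max_iter, cv, cv_target)
    K <- K * (cv_target / cv)^2
    sigma <- conductivity_set(sigma$base[1], sigma$base[2], sigma$base[3],
                              sigma$base[4], sigma_b = sigma$sigma_b, K = K)
    cv <- run_cv(sigma)
  }
  attr(sigma, "cv") <- cv
  attr(sigma, "iterations") <- it
  sigma
}
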