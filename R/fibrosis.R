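#' Fibrosis pattern specification
#'
#' Four histology archetypes drawn from fractal Perlin noise.  The per-type
#' presets (octaves, feature size, fiber anisotropy) reproduce the
#' qualitative appearance of each archetype: compact scar is one large
#' smooth blob; diffuse fibrosis is fine multi-octave speckle; interstitial
#' strands and patchy clusters are elongated along the local fiber
#' direction.
#'
#' @param type one of `"compact"`, `"diffuse"`, `"interstitial"`, `"patchy"`.
#' @param density target fibrotic element fraction in `[0, 1]` (study levels:
#'   0.10, 0.35, 0.60).
#' @param seed integer noise seed.
#' @param feature_size correlation length of the base octave, mm (preset by
#'   type when `NULL`).
#' @param octaves number of noise octaves (preset by type when `NULL`).
#' @param fiber_anisotropy ratio (at least 1); coordinates are compressed by
#'   this factor along the fiber direction before the noise lookup,
#'   elongating features along fibers (preset by type when `NULL`).
#' @return Object of class `fibrosis_spec`.
#' @export
fibrosis_spec <- function(type = c("compact", "diffuse", "interstitial", "patchy"),
                          density, seed = 1, feature_size = NULL, octaves = NULL,
                          fiber_anisotropy = NULL) {
  type <- match.arg(type)
  .stop_if(density < 0 || density > 1, "density must be in [0, 1]")
  presets <- list(
    compact      = list(feature_size = 8, octaves = 1L, fiber_anisotropy = 1),
    diffuse      = list(feature_size = 1, octaves = 4L, fiber_anisotropy = 1),
    interstitial = list(feature_size = 2, octaves = 3L, fiber_anisotropy = 6),
    patchy       = list(feature_size = 4, octaves = 2L, fiber_anisotropy = 3))
  p <- presets[[type]]
  if (!is.null(feature_size)) p$feature_size <- feature_size
  if (!is.null(octaves)) p$octaves <- as.integer(octaves)
  if (!is.null(fiber_anisotropy)) p$fiber_anisotropy <- fiber_anisotropy
  .stop_if(p$feature_size <= 0, "feature_size must be positive")
  .stop_if(p$octaves < 1, "octaves must be >= 1")
  .stop_if(p$fiber_anisotropy < 1, "fiber_anisotropy must be >= 1")
  structure(list(type = type, density = density, seed = as.integer(seed),
                 feature_size = p$feature_size, octaves = p$octaves,
                 fiber_anisotropy = p$fiber_anisotropy), class = "fibrosis_spec")
}

#' Three-dimensional fractal Perlin noise at element centroids
#'
#' Gradient noise summed over `octaves` harmonics (amplitude halved and
#' frequency doubled per octave), evaluated on x, y and z coordinates
#' pre-scaled by `1/feature_size`.  For fiber-aligned archetypes the
#' coordinates are first compressed by `fiber_anisotropy` along the local
#' fiber direction, which stretches the resulting features along fibers.
#'
#' @param centroids `E x 3` element centroids, mm.
#' @param field an `lapw_fiber_field` (only needed when
#'   `fiber_anisotropy > 1`).
#' @param spec a [fibrosis_spec()].
#' @return Numeric vector of length `E`.
#' @export
perlin_field_3d <- function(centroids, field = NULL, spec) {
  stopifnot(inherits(spec, "fibrosis_spec"))
  centroids <- as.matrix(centroids)
  .stop_if(nrow(centroids) < 1, "need at least one element")
  x <- centroids
  if (spec$fiber_anisotropy > 1) {
    .stop_if(is.null(field), "a fiber field is required when fiber_anisotropy > 1")
    f <- field$f
    proj <- rowSums(x * f)
    x <- x + (1 / spec$fiber_anisotropy - 1) * proj * f
  }
  .perlin_fractal3d(x / spec$feature_size, spec$octaves, spec$seed)
}

#' Generate a fibrosis pattern on a mesh
#'
#' The `round(density * E)` elements with the largest noise values are
#' fibrotic (order-statistic thresholding at the `(1 - density)` quantile),
#' so the achieved density is exact to within one element for every type and
#' seed.
#'
#' @param mesh a [volume_mesh()].
#' @param field fiber field (for anisotropic types).
#' @param spec a [fibrosis_spec()].
#' @return Object of class `fibrosis_pattern`: logical `fibrotic` per
#'   element, `achieved_density`, and the spec.
#' @export
generate_pattern <- function(mesh, field = NULL, spec) {
  stopifnot(inherits(mesh, "lapw_volume_mesh"))
  noise <- perlin_field_3d(mesh_centroids(mesh), field, spec)
  ne <- length(noise)
  k <- round(spec$density * ne)
  fib <- logical(ne)
  if (k > 0) fib[order(noise, decreasing = TRUE)[seq_len(k)]] <- TRUE
  structure(list(fibrotic = fib, achieved_density = k / ne, spec = spec),
            class = "fibrosis_pattern")
}

#' @export
print.fibrosis_pattern <- function(x, ...) {
  cat(sprintf("Fibrosis pattern (%s, seed %d): %.1f%% of %d elements\n",
              x$spec$type, x$spec$seed, 100 * x$achieved_density,
              length(x$fibrotic)))
  invisible(x)
}

#' Apply a fibrosis pattern as a percolation subdomain
#'
#' Fibrotic elements are tagged subdomain 2 and skipped by the solver
#' assembly, so transmembrane voltage and current are never computed there;
#' no-flux internal boundaries arise implicitly and propagation percolates
#' around the holes.  The connectivity of the remaining conductive elements
#' (face adjacency) is computed and reported so callers can verify the
#' stimulus region still reaches the rest of the tissue.
#'
#' @param mesh a [volume_mesh()].
#' @param pattern a `fibrosis_pattern` from [generate_pattern()].
#' @return The tagged [volume_mesh()], with attributes `component` (per
#'   conductive element component id, `NA` for fibrotic elements) and
#'   `component_sizes`.
#' @export
apply_percolation <- function(mesh, pattern) {
  stopifnot(inherits(mesh, "lapw_volume_mesh"), inherits(pattern, "fibrosis_pattern"))
  .stop_if(length(pattern$fibrotic) != nrow(mesh$tets),
           "pattern does not match the mesh (%d vs %d elements)",
           length(pattern$fibrotic), nrow(mesh$tets))
  .stop_if(all(pattern$fibrotic), "pattern leaves no conductive tissue")
  sub <- mesh$subdomain
  sub[pattern$fibrotic] <- 2L
  out <- volume_mesh(mesh$vertices, mesh$tets, sub, mesh$transmural)
  comp <- .element_components(out)
  attr(out, "component") <- comp
  attr(out, "component_sizes") <- sort(table(comp), decreasing = TRUE)
  out
}

# connected components of the conductive (subdomain-1) element face-adjacency
.element_components <- function(mesh) {
  cond <- which(mesh$subdomain == 1L)
  tets <- mesh$tets[cond, , drop = FALSE]
  ne <- nrow(tets)
  f <- rbind(tets[, c(2, 3, 4)], tets[, c(1, 3, 4)],
             tets[, c(1, 2, 4)], tets[, c(1, 2, 3)])
  lo <- pmin(f[, 1], f[, 2], f[, 3])
  hi <- pmax(f[, 1], f[, 2], f[, 3])
  key <- paste(lo, f[, 1] + f[, 2] + f[, 3] - lo - hi, hi)
  owner <- rep(seq_len(ne), 4)
  parent <- seq_len(ne)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  for (grp in split(owner, key)) if (length(grp) == 2) {
    r1 <- find(grp[1]); r2 <- find(grp[2])
    if (r1 != r2) parent[r2] <- r1
  }
  roots <- vapply(seq_len(ne), find, 1L)
  comp <- rep(NA_integer_, nrow(mesh$tets))
  comp[cond] <- match(roots, unique(roots))
  comp
}
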