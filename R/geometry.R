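#' Point cloud container
#'
#' Wraps an `N x 3` coordinate matrix (mm) with optional unit normals.
#'
#' @param points numeric matrix, `N x 3`, coordinates in mm.
#' @param normals optional `N x 3` matrix of unit normals.
#' @return An object of class `lapw_point_cloud`.
#' @export
point_cloud <- function(points, normals = NULL) {
  points <- as.matrix(points)
  .stop_if(ncol(points) != 3, "points must be an N x 3 matrix")
  .stop_if(nrow(points) < 1, "empty point cloud")
  .stop_if(!all(is.finite(points)), "point coordinates must be finite")
  storage.mode(points) <- "double"
  if (!is.null(normals)) {
    normals <- as.matrix(normals)
    .stop_if(!identical(dim(normals), dim(points)), "normals must match points")
    nn <- sqrt(rowSums(normals^2))
    .stop_if(any(abs(nn - 1) > 1e-8), "normals must be unit length")
  }
  structure(list(points = points, normals = normals), class = "lapw_point_cloud")
}

#' @export
print.lapw_point_cloud <- function(x, ...) {
  cat(sprintf("Point cloud: %d points (mm)%s\n", nrow(x$points),
              if (is.null(x$normals)) "" else ", with normals"))
  invisible(x)
}

#' Downsample a point cloud to a minimum spacing
#'
#' Greedy insertion in input order: a point is kept when it lies at least
#' `min_spacing` from every point kept so far, so the retained set is a
#' deterministic subset with minimum pairwise distance >= `min_spacing`.
#' Dense electroanatomical clouds (about 1 mm spacing) are typically thinned
#' to about 3.5 mm before surface reconstruction so that extrusion along
#' noisy local normals cannot self-intersect.
#'
#' @param cloud a [point_cloud()].
#' @param min_spacing minimum pairwise distance, mm.
#' @return A [point_cloud()] of the retained points, with attribute `kept`
#'   (indices into the input).
#' @export
downsample_pcd <- function(cloud, min_spacing) {
  stopifnot(inherits(cloud, "lapw_point_cloud"))
  .stop_if(length(min_spacing) != 1 || min_spacing <= 0, "min_spacing must be a positive scalar")
  keep <- .greedy_downsample(cloud$points, min_spacing)
  out <- point_cloud(cloud$points[keep, , drop = FALSE],
                     if (is.null(cloud$normals)) NULL else cloud$normals[keep, , drop = FALSE])
  attr(out, "kept") <- keep
  out
}

# principal-axis frame of a cloud: right-handed basis (e1, e2, e3) with e3 the
# least-variance (sheet normal) direction
.pca_frame <- function(points) {
  ctr <- colMeans(points)
  sv <- svd(sweep(points, 2, ctr))
  e <- sv$v
  # fix the SVD sign ambiguity: the out-of-plane axis points along the
  # positive side of its dominant global component (flip e2 to stay
  # right-handed), so "outward" is reproducible across runs
  k <- which.max(abs(e[, 3]))
  if (e[k, 3] < 0) { e[, 3] <- -e[, 3]; e[, 2] <- -e[, 2] }
  if (det(e) < 0) e[, 1] <- -e[, 1]
  list(center = ctr, basis = e, sdev = sv$d / sqrt(max(1, nrow(points) - 1)))
}

#' Surface mesh container
#'
#' @param vertices `V x 3` matrix, mm.
#' @param triangles `T x 3` integer matrix of vertex indices (1-based).
#' @param vertex_normals optional `V x 3` unit normals; computed
#'   (area-weighted) when missing.
#' @return Object of class `lapw_surface`.
#' @export
surface_mesh <- function(vertices, triangles, vertex_normals = NULL) {
  vertices <- as.matrix(vertices); storage.mode(vertices) <- "double"
  triangles <- as.matrix(triangles); storage.mode(triangles) <- "integer"
  .stop_if(ncol(vertices) != 3 || ncol(triangles) != 3, "bad dimensions")
  a <- .tri_areas(vertices, triangles)
  .stop_if(any(a <= 1e-9), "degenerate triangle (area <= 1e-9 mm^2)")
  if (is.null(vertex_normals)) vertex_normals <- .vertex_normals(vertices, triangles)
  structure(list(vertices = vertices, triangles = triangles,
                 vertex_normals = vertex_normals), class = "lapw_surface")
}

#' @export
print.lapw_surface <- function(x, ...) {
  cat(sprintf("Surface mesh: %d vertices, %d triangles (mm)\n",
              nrow(x$vertices), nrow(x$triangles)))
  invisible(x)
}

.tri_cross <- function(vertices, triangles) {
  p1 <- vertices[triangles[, 1], , drop = FALSE]
  u <- vertices[triangles[, 2], , drop = FALSE] - p1
  v <- vertices[triangles[, 3], , drop = FALSE] - p1
  cbind(u[, 2] * v[, 3] - u[, 3] * v[, 2],
        u[, 3] * v[, 1] - u[, 1] * v[, 3],
        u[, 1] * v[, 2] - u[, 2] * v[, 1])
}

.tri_areas <- function(vertices, triangles) {
  0.5 * sqrt(rowSums(.tri_cross(vertices, triangles)^2))
}

.face_normals <- function(vertices, triangles) {
  cr <- .tri_cross(vertices, triangles)
  cr / sqrt(rowSums(cr^2))
}

# area-weighted vertex normals
.vertex_normals <- function(vertices, triangles) {
  cr <- .tri_cross(vertices, triangles)   # length = 2 * area, direction = face normal
  vn <- matrix(0, nrow(vertices), 3)
  for (k in 1:3) {
    idx <- triangles[, k]
    for (d in 1:3) vn[, d] <- vn[, d] + tapply_add(idx, cr[, d], nrow(vertices))
  }
  len <- sqrt(rowSums(vn^2))
  .stop_if(any(len == 0), "vertex with no incident triangles or cancelling normals")
  vn / len
}

# fast grouped sum onto a fixed-length vector
tapply_add <- function(idx, val, n) {
  out <- numeric(n)
  acc <- rowsum(val, idx)
  out[as.integer(rownames(acc))] <- acc
  out
}

#' Reconstruct a sheet surface from a point cloud
#'
#' The cloud is aligned to its principal axes, projected onto the principal
#' plane, Delaunay-triangulated in 2-D, and lifted back to 3-D.  This is a
#' deterministic replacement for ball-pivot reconstruction that is guaranteed
#' manifold and single-sheet for sheet-like clouds such as the left atrial
#' posterior wall.  Every input point becomes a mesh vertex; normals are
#' oriented towards the sheet's outward (third principal axis) side.
#'
#' @param cloud a [point_cloud()].
#' @param max_aspect reject clouds whose out-of-plane extent exceeds this
#'   fraction of the in-plane extent (projection would fold).
#' @return A [surface_mesh()].
#' @export
reconstruct_surface <- function(cloud, max_aspect = 0.8) {
  stopifnot(inherits(cloud, "lapw_point_cloud"))
  pts <- cloud$points
  .stop_if(nrow(pts) < 3, "surface reconstruction needs at least 3 points")
  fr <- .pca_frame(pts)
  .stop_if(fr$sdev[2] < 1e-9, "points are collinear; no surface is defined")
  .stop_if(fr$sdev[3] > max_aspect * fr$sdev[2],
           "cloud is not sheet-like (out-of-plane spread %.3g vs in-plane %.3g)",
           fr$sdev[3], fr$sdev[2])
  loc <- sweep(pts, 2, fr$center) %*% fr$basis
  tri <- .delaunay2d(loc[, 1], loc[, 2])
  # orient counter-clockwise in the projected plane -> consistent winding,
  # face normals towards +e3 (outward)
  v1 <- tri[, 1]; v2 <- tri[, 2]; v3 <- tri[, 3]
  det2 <- (loc[v2, 1] - loc[v1, 1]) * (loc[v3, 2] - loc[v1, 2]) -
          (loc[v2, 2] - loc[v1, 2]) * (loc[v3, 1] - loc[v1, 1])
  flip <- det2 < 0
  tri[flip, ] <- tri[flip, c(1, 3, 2)]
  mesh <- surface_mesh(pts, tri)
  attr(mesh, "frame") <- fr
  mesh
}

# edge table: rows (vmin, vmax, triangle)
.surface_edges <- function(triangles) {
  e <- rbind(triangles[, c(1, 2)], triangles[, c(2, 3)], triangles[, c(3, 1)])
  cbind(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]),
        rep(seq_len(nrow(triangles)), 3))
}

.is_connected_surface <- function(triangles) {
  nt <- nrow(triangles)
  if (nt <= 1) return(TRUE)
  ed <- .surface_edges(triangles)
  key <- ed[, 1] * (max(triangles) + 1) + ed[, 2]
  parent <- seq_len(nt)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  sp <- split(ed[, 3], key)
  for (tris in sp) if (length(tris) > 1) {
    r <- find(tris[1])
    for (t in tris[-1]) { r2 <- find(t); if (r2 != r) parent[r2] <- r }
  }
  length(unique(vapply(seq_len(nt), find, 1L))) == 1
}

#' Remove spike vertices that would break extrusion
#'
#' Vertices whose incident triangle normals span more than `max_normal_angle`
#' are removed and the surface re-triangulated from the remaining points
#' (same principal-plane projection as [reconstruct_surface()]).  Such spikes
#' are the points that cause overlapping surfaces when the sheet is extruded
#' along vertex normals.
#'
#' @param mesh a [surface_mesh()] from [reconstruct_surface()].
#' @param max_normal_angle maximum allowed spread of incident face normals,
#'   degrees (default 60).
#' @return Cleaned [surface_mesh()] with attribute `removed` (count).
#' @export
clean_surface <- function(mesh, max_normal_angle = 60) {
  stopifnot(inherits(mesh, "lapw_surface"))
  fn <- .face_normals(mesh$vertices, mesh$triangles)
  nv <- nrow(mesh$vertices)
  spread <- numeric(nv)
  inc <- split(rep(seq_len(nrow(mesh$triangles)), 3), as.vector(mesh$triangles))
  for (v in names(inc)) {
    f <- inc[[v]]
    if (length(f) < 2) next
    g <- fn[f, , drop = FALSE]
    cmin <- min(tcrossprod(g))
    spread[as.integer(v)] <- acos(max(-1, min(1, cmin))) * 180 / pi
  }
  bad <- which(spread > max_normal_angle)
  if (length(bad) == 0) {
    attr(mesh, "removed") <- 0L
    return(mesh)
  }
  keep <- setdiff(seq_len(nv), bad)
  .stop_if(length(keep) < 3, "cleaning removed too many vertices")
  out <- reconstruct_surface(point_cloud(mesh$vertices[keep, , drop = FALSE]))
  .stop_if(!.is_connected_surface(out$triangles),
           "vertex removal disconnected the surface")
  attr(out, "removed") <- length(bad)
  out
}

#' Extrude a sheet surface to a wall-thickness prism shell
#'
#' Each vertex is offset by `thickness` along its area-weighted vertex
#' normal, turning every triangle into a prism.  The left atrial posterior
#' wall is typically 2.3 mm thick, which is the default used by the
#' pipeline.  The offset is checked for self-intersection (flipped or
#' degenerate prisms), which signals that the surface still needs cleaning.
#'
#' @param mesh a [surface_mesh()].
#' @param thickness extrusion distance, mm (> 0).
#' @return Object of class `lapw_shell`: vertices (`2V x 3`, base then top),
#'   prism connectivity (`T x 6`), per-vertex transmural coordinate (0 base,
#'   1 top), and the thickness.
#' @export
extrude_surface <- function(mesh, thickness) {
  stopifnot(inherits(mesh, "lapw_surface"))
  .stop_if(length(thickness) != 1 || thickness <= 0, "thickness must be a positive scalar")
  v <- mesh$vertices
  nv <- nrow(v)
  top <- v + thickness * mesh$vertex_normals
  prisms <- cbind(mesh$triangles, mesh$triangles + nv)
  shell <- structure(list(vertices = rbind(v, top), prisms = prisms,
                          transmural = c(rep(0, nv), rep(1, nv)),
                          thickness = thickness), class = "lapw_shell")
  # self-intersection guard: no prism may flip or collapse
  vols <- .prism_tet_volumes(shell)
  .stop_if(any(vols <= 0),
           "extrusion self-intersects (%d inverted tetrahedra); clean the surface first",
           sum(vols <= 0))
  # flipped top triangles indicate local fold-over even without inversion
  fn_base <- .face_normals(v, mesh$triangles)
  fn_top <- .face_normals(top, mesh$triangles)
  .stop_if(any(rowSums(fn_base * fn_top) <= 0), "extrusion folds the offset surface")
  shell
}

#' @export
print.lapw_shell <- function(x, ...) {
  cat(sprintf("Prism shell: %d prisms, thickness %.3g mm\n",
              nrow(x$prisms), x$thickness))
  invisible(x)
}

# the lexicographic prism split used by tetrahedralize(), as index triples
.split_prism <- function(p) {
  # rotate so the smallest global index is bottom-first; bottom rotation and
  # orientation-preserving bottom/top swap are the allowed transforms
  rot <- function(q) q[c(2, 3, 1, 5, 6, 4)]
  swap <- function(q) q[c(4, 6, 5, 1, 3, 2)]
  for (k in 1:6) {
    if (which.min(p) == 1) break
    p <- if (which.min(p) %in% c(2, 3)) rot(p) else swap(p)
  }
  b0 <- p[1]; b1 <- p[2]; b2 <- p[3]; t0 <- p[4]; t1 <- p[5]; t2 <- p[6]
  # quad (b1,b2,t2,t1) takes the diagonal through its smallest vertex
  if (min(b1, t2) < min(b2, t1)) {
    rbind(c(b0, b1, b2, t2), c(b0, b1, t2, t1), c(b0, t1, t2, t0))
  } else {
    rbind(c(b0, b1, b2, t1), c(b0, t1, b2, t2), c(b0, t1, t2, t0))
  }
}

.tet_volumes <- function(vertices, tets) {
  a <- vertices[tets[, 2], , drop = FALSE] - vertices[tets[, 1], , drop = FALSE]
  b <- vertices[tets[, 3], , drop = FALSE] - vertices[tets[, 1], , drop = FALSE]
  d <- vertices[tets[, 4], , drop = FALSE] - vertices[tets[, 1], , drop = FALSE]
  (a[, 1] * (b[, 2] * d[, 3] - b[, 3] * d[, 2]) -
   a[, 2] * (b[, 1] * d[, 3] - b[, 3] * d[, 1]) +
   a[, 3] * (b[, 1] * d[, 2] - b[, 2] * d[, 1])) / 6
}

.prism_tets <- function(shell) {
  do.call(rbind, lapply(seq_len(nrow(shell$prisms)),
                        function(i) .split_prism(shell$prisms[i, ])))
}

.prism_tet_volumes <- function(shell) .tet_volumes(shell$vertices, .prism_tets(shell))

#' Volume of a prism shell
#' @param shell an `lapw_shell`.
#' @return Total volume, mm^3.
#' @export
shell_volume <- function(shell) sum(.prism_tet_volumes(shell))

#' Volume mesh container
#'
#' @param vertices `V x 3` mm.
#' @param tets `E x 4` integer connectivity, positively oriented.
#' @param subdomain integer element tags: 1 conductive tissue, 2 fibrotic
#'   (excluded from the monodomain solve).
#' @param transmural optional per-vertex transmural coordinate in `[0, 1]`
#'   (0 endocardial base, 1 epicardial top), used by the fiber rule.
#' @return Object of class `lapw_volume_mesh`.
#' @export
volume_mesh <- function(vertices, tets, subdomain = NULL, transmural = NULL) {
  vertices <- as.matrix(vertices); storage.mode(vertices) <- "double"
  tets <- as.matrix(tets); storage.mode(tets) <- "integer"
  .stop_if(ncol(tets) != 4, "tets must be E x 4")
  if (is.null(subdomain)) subdomain <- rep(1L, nrow(tets))
  .stop_if(!all(subdomain %in% c(1L, 2L)), "subdomain tags must be 1 or 2")
  vol <- .tet_volumes(vertices, tets)
  .stop_if(any(vol <= 0), "%d non-positively-oriented tetrahedra", sum(vol <= 0))
  structure(list(vertices = vertices, tets = tets,
                 subdomain = as.integer(subdomain), transmural = transmural),
            class = "lapw_volume_mesh")
}

#' @export
print.lapw_volume_mesh <- function(x, ...) {
  cat(sprintf("Volume mesh: %d vertices, %d tets (%d fibrotic), volume %.4g mm^3\n",
              nrow(x$vertices), nrow(x$tets), sum(x$subdomain == 2L),
              sum(.tet_volumes(x$vertices, x$tets))))
  invisible(x)
}

#' Tetrahedralize a prism shell
#'
#' Splits each prism into 3 tetrahedra with globally consistent quad
#' diagonals (each quad face takes the diagonal through its smallest global
#' vertex index), so adjacent prisms conform and no hanging faces arise.
#' Total volume is preserved exactly and all tetrahedra are positively
#' oriented.
#'
#' @param shell an `lapw_shell` from [extrude_surface()].
#' @return A [volume_mesh()].
#' @export
tetrahedralize <- function(shell) {
  stopifnot(inherits(shell, "lapw_shell"))
  tets <- .prism_tets(shell)
  volume_mesh(shell$vertices, tets, transmural = shell$transmural)
}

#' Uniform (red) refinement of a tetrahedral mesh
#'
#' Every tetrahedron is split into 8 via edge midpoints (Bey's rule for the
#' interior octahedron).  Volume is preserved exactly, subdomain tags are
#' inherited, and edge lengths halve per level; two levels bring a
#' millimetre-scale mesh to the 200-300 micron elements that monodomain
#' convergence requires.
#'
#' @param mesh a [volume_mesh()].
#' @param levels number of refinement passes (>= 0).
#' @return A [volume_mesh()] with `8^levels` times as many elements.
#' @export
refine_uniform <- function(mesh, levels = 1) {
  stopifnot(inherits(mesh, "lapw_volume_mesh"))
  .stop_if(levels < 0, "levels must be >= 0")
  for (l in seq_len(levels)) mesh <- .refine_once(mesh)
  mesh
}

.refine_once <- function(mesh) {
  v <- mesh$vertices; tets <- mesh$tets
  nv <- nrow(v)
  ep <- rbind(tets[, c(1, 2)], tets[, c(1, 3)], tets[, c(1, 4)],
              tets[, c(2, 3)], tets[, c(2, 4)], tets[, c(3, 4)])
  ekey <- paste(pmin(ep[, 1], ep[, 2]), pmax(ep[, 1], ep[, 2]))
  uk <- unique(ekey)
  mid_id <- nv + match(ekey, uk)
  first <- !duplicated(ekey)
  mids <- (v[ep[first, 1], , drop = FALSE] + v[ep[first, 2], , drop = FALSE]) / 2
  v2 <- rbind(v, mids[order(match(ekey[first], uk)), , drop = FALSE])
  ne <- nrow(tets)
  m01 <- mid_id[seq_len(ne)];          m02 <- mid_id[ne + seq_len(ne)]
  m03 <- mid_id[2 * ne + seq_len(ne)]; m12 <- mid_id[3 * ne + seq_len(ne)]
  m13 <- mid_id[4 * ne + seq_len(ne)]; m23 <- mid_id[5 * ne + seq_len(ne)]
  x0 <- tets[, 1]; x1 <- tets[, 2]; x2 <- tets[, 3]; x3 <- tets[, 4]
  child <- rbind(
    cbind(x0, m01, m02, m03), cbind(m01, x1, m12, m13),
    cbind(m02, m12, x2, m23), cbind(m03, m13, m23, x3),
    cbind(m01, m02, m03, m13), cbind(m01, m02, m12, m13),
    cbind(m02, m03, m13, m23), cbind(m02, m12, m13, m23))
  # fix orientation of any inverted child (volume magnitude unchanged)
  vol <- .tet_volumes(v2, child)
  neg <- vol < 0
  child[neg, c(3, 4)] <- child[neg, c(4, 3)]
  sub2 <- rep(mesh$subdomain, 8)
  tm <- NULL
  if (!is.null(mesh$transmural)) {
    tm_m <- (mesh$transmural[ep[first, 1]] + mesh$transmural[ep[first, 2]]) / 2
    tm <- c(mesh$transmural, tm_m[order(match(ekey[first], uk))])
  }
  volume_mesh(v2, child, sub2, tm)
}

#' Edge lengths of a volume mesh
#' @param mesh a [volume_mesh()].
#' @return Numeric vector of unique edge lengths, mm.
#' @export
mesh_edge_lengths <- function(mesh) {
  tets <- mesh$tets
  ep <- rbind(tets[, c(1, 2)], tets[, c(1, 3)], tets[, c(1, 4)],
              tets[, c(2, 3)], tets[, c(2, 4)], tets[, c(3, 4)])
  ep <- unique(cbind(pmin(ep[, 1], ep[, 2]), pmax(ep[, 1], ep[, 2])))
  sqrt(rowSums((mesh$vertices[ep[, 1], , drop = FALSE] -
                mesh$vertices[ep[, 2], , drop = FALSE])^2))
}

#' Boundary facets of a volume mesh
#' @param mesh a [volume_mesh()].
#' @return Integer matrix `F x 3` of triangle facets appearing in exactly one
#'   tetrahedron.
#' @export
mesh_boundary_facets <- function(mesh) {
  tets <- mesh$tets
  f <- rbind(tets[, c(2, 3, 4)], tets[, c(1, 4, 3)],
             tets[, c(1, 2, 4)], tets[, c(1, 3, 2)])
  lo <- pmin(f[, 1], f[, 2], f[, 3])
  hi <- pmax(f[, 1], f[, 2], f[, 3])
  key <- paste(lo, f[, 1] + f[, 2] + f[, 3] - lo - hi, hi)
  f[key %in% names(which(table(key) == 1)), , drop = FALSE]
}

#' Element centroids
#' @param mesh a [volume_mesh()].
#' @return `E x 3` matrix of tetrahedron centroids, mm.
#' @export
mesh_centroids <- function(mesh) {
  (mesh$vertices[mesh$tets[, 1], , drop = FALSE] +
   mesh$vertices[mesh$tets[, 2], , drop = FALSE] +
   mesh$vertices[mesh$tets[, 3], , drop = FALSE] +
   mesh$vertices[mesh$tets[, 4], , drop = FALSE]) / 4
}

#' Build a volume mesh from a point cloud in one call
#'
#' Convenience wrapper chaining [downsample_pcd()], [reconstruct_surface()],
#' [clean_surface()], [extrude_surface()], [tetrahedralize()] and
#' [refine_uniform()].
#'
#' @param cloud a [point_cloud()].
#' @param spacing downsampling minimum distance, mm (default 3.5).
#' @param thickness wall thickness, mm (default 2.3).
#' @param refine refinement levels (default 2).
#' @param max_normal_angle cleaning threshold, degrees.
#' @return A [volume_mesh()].
#' @export
build_mesh <- function(cloud, spacing = 3.5, thickness = 2.3, refine = 2,
                       max_normal_angle = 60) {
  ds <- downsample_pcd(cloud, spacing)
  surf <- clean_surface(reconstruct_surface(ds), max_normal_angle)
  refine_uniform(tetrahedralize(extrude_surface(surf, thickness)), refine)
}
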