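test_that("greedy downsampling enforces the minimum spacing", {
  pc <- make_sheet_pcd(sheet_spec(20, 20, point_spacing = 1))
  ds <- downsample_pcd(pc, 3.5)
  d <- as.matrix(dist(ds$points)); diag(d) <- Inf
  expect_gte(min(d), 3.5)
  # retained points are a subset in input order
  expect_true(all(diff(attr(ds, "kept")) > 0))
})

test_that("downsampling below the existing spacing is the identity", {
  pc <- make_sheet_pcd(sheet_spec(10, 10, point_spacing = 1))
  expect_equal(downsample_pcd(pc, 0.5)$points, pc$points)
  one <- point_cloud(matrix(c(1, 2, 3), 1))
  expect_equal(downsample_pcd(one, 10)$points, one$points)
})

test_that("downsampling is idempotent", {
  pc <- make_sheet_pcd(sheet_spec(20, 20, point_spacing = 1,
                                  positional_noise_sd = 0.1, seed = 5))
  once <- downsample_pcd(pc, 3.5)
  twice <- downsample_pcd(once, 3.5)
  expect_equal(twice$points, once$points)
})

test_that("surface reconstruction triangulates sheet-like clouds", {
  tri3 <- reconstruct_surface(point_cloud(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0))))
  expect_equal(nrow(tri3$triangles), 1)
  grid <- reconstruct_surface(make_sheet_pcd(sheet_spec(6, 4, point_spacing = 1)))
  expect_equal(nrow(grid$triangles), 2 * 6 * 4)   # 2 (n-1)(m-1)
  expect_equal(nrow(grid$vertices), 35)           # every input point kept
  col <- point_cloud(cbind(0:5, 0, 0))
  expect_error(reconstruct_surface(col), "collinear")
})

test_that("reconstructed surfaces are manifold with consistent winding", {
  surf <- reconstruct_surface(make_sheet_pcd(sheet_spec(10, 10, point_spacing = 1,
                                                        positional_noise_sd = 0.05,
                                                        seed = 3)))
  ed <- lapwsim:::.surface_edges(surf$triangles)
  key <- paste(ed[, 1], ed[, 2])
  expect_lte(max(table(key)), 2)                  # each edge in <= 2 triangles
  # consistent orientation: all face normals on the same side
  fn <- lapwsim:::.face_normals(surf$vertices, surf$triangles)
  expect_true(all(fn[, 3] > 0))
})

test_that("clean_surface removes spike vertices and reports the count", {
  pc <- make_sheet_pcd(sheet_spec(10, 10, point_spacing = 1))
  smooth <- reconstruct_surface(pc)
  expect_equal(attr(clean_surface(smooth, 60), "removed"), 0L)
  expect_equal(attr(clean_surface(smooth, 180), "removed"), 0L)
  pts <- pc$points
  pts[pts[, 1] == 5 & pts[, 2] == 5, 3] <- 0.6    # one spike, normal spread > 60 deg
  spiky <- reconstruct_surface(point_cloud(pts))
  cleaned <- clean_surface(spiky, 60)
  expect_equal(attr(cleaned, "removed"), 1L)
  expect_equal(nrow(cleaned$vertices), nrow(pts) - 1)
  expect_equal(attr(clean_surface(spiky, 180), "removed"), 0L)
})

test_that("extrusion offsets by the exact thickness and checks self-intersection", {
  surf <- reconstruct_surface(make_sheet_pcd(sheet_spec(10, 10, point_spacing = 1)))
  shell <- extrude_surface(surf, 2.3)
  nv <- nrow(surf$vertices)
  off <- sqrt(rowSums((shell$vertices[nv + seq_len(nv), ] -
                       shell$vertices[seq_len(nv), ])^2))
  expect_lt(abs(mean(off) - 2.3), 1e-9)
  expect_equal(shell_volume(shell), 10 * 10 * 2.3, tolerance = 1e-9)
  expect_error(extrude_surface(surf, 0), "thickness")
  # concave cap tighter than the wall thickness must self-intersect
  th <- seq(-0.6, 0.6, length.out = 11)
  g <- expand.grid(a = th, b = th)
  cap <- cbind(1.5 * sin(g$a), 1.5 * sin(g$b), -1.5 * cos(g$a) * cos(g$b))
  expect_error(extrude_surface(reconstruct_surface(point_cloud(cap)), 2.3),
               "self-intersect")
})

test_that("prism splitting yields 3 conforming positive tets per prism", {
  one <- reconstruct_surface(point_cloud(rbind(c(0, 0, 0), c(2, 0, 0), c(0, 2, 0))))
  shell <- extrude_surface(one, 1)
  mesh <- tetrahedralize(shell)
  expect_equal(nrow(mesh$tets), 3)
  expect_equal(sum(lapwsim:::.tet_volumes(mesh$vertices, mesh$tets)),
               shell_volume(shell), tolerance = 1e-12)
  surf <- reconstruct_surface(make_sheet_pcd(sheet_spec(8, 8, point_spacing = 1)))
  mesh2 <- tetrahedralize(extrude_surface(surf, 2.3))
  expect_equal(nrow(mesh2$tets), 3 * nrow(surf$triangles))
  expect_gt(min(lapwsim:::.tet_volumes(mesh2$vertices, mesh2$tets)), 0)
  # conformity: interior faces shared by exactly 2 tets
  f <- rbind(mesh2$tets[, c(2, 3, 4)], mesh2$tets[, c(1, 3, 4)],
             mesh2$tets[, c(1, 2, 4)], mesh2$tets[, c(1, 2, 3)])
  lo <- pmin(f[, 1], f[, 2], f[, 3]); hi <- pmax(f[, 1], f[, 2], f[, 3])
  key <- paste(lo, f[, 1] + f[, 2] + f[, 3] - lo - hi, hi)
  expect_lte(max(table(key)), 2)
})

test_that("uniform refinement preserves volume and splits 1 tet into 8", {
  surf <- reconstruct_surface(point_cloud(rbind(c(0, 0, 0), c(2, 0, 0), c(0, 2, 0))))
  mesh <- tetrahedralize(extrude_surface(surf, 1))
  expect_equal(refine_uniform(mesh, 0)$tets, mesh$tets)
  r1 <- refine_uniform(volume_mesh(mesh$vertices, mesh$tets[1, , drop = FALSE]), 1)
  expect_equal(nrow(r1$tets), 8)
  expect_equal(sum(lapwsim:::.tet_volumes(r1$vertices, r1$tets)),
               lapwsim:::.tet_volumes(mesh$vertices, mesh$tets)[1],
               tolerance = 1e-12)
  r2 <- refine_uniform(mesh, 2)
  expect_equal(nrow(r2$tets), 3 * 8^2)
  expect_equal(sum(lapwsim:::.tet_volumes(r2$vertices, r2$tets)),
               shell_volume(extrude_surface(surf, 1)), tolerance = 1e-9)
  # edge lengths halve per level
  expect_equal(max(mesh_edge_lengths(r1)), max(mesh_edge_lengths(mesh)) / 2,
               tolerance = 1e-12)
  # subdomain tags inherited
  tagged <- volume_mesh(mesh$vertices, mesh$tets, c(1L, 2L, 1L), mesh$transmural)
  expect_equal(refine_uniform(tagged, 1)$subdomain,
               rep(c(1L, 2L, 1L), 8))
})

test_that("full pipeline volume equals planform area times thickness", {
  pc <- make_sheet_pcd(sheet_spec(20, 20, point_spacing = 1,
                                  positional_noise_sd = 0.02, seed = 11))
  mesh <- build_mesh(pc, spacing = 3.5, thickness = 2.3, refine = 1)
  vol <- sum(lapwsim:::.tet_volumes(mesh$vertices, mesh$tets))
  # planform area of the reconstructed (downsampled) sheet, not the nominal extent
  ds <- downsample_pcd(pc, 3.5)
  surf <- clean_surface(reconstruct_surface(ds), 60)
  area <- sum(lapwsim:::.tri_areas(surf$vertices, surf$triangles))
  expect_lt(abs(vol - area * 2.3) / (area * 2.3), 1e-3)
})
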