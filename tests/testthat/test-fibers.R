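test_that("transmural fiber rule gives orthonormal right-handed triads", {
  mesh <- slab_coarse()
  f0 <- template_field(mesh, 0, 0)
  # flat slab, zero angle everywhere: fibers along +x
  expect_lt(max(abs(f0$f[, 1] - 1)), 1e-8)
  fld <- template_field(mesh, -30, 30)
  dots <- c(abs(rowSums(fld$f * fld$s)), abs(rowSums(fld$f * fld$n)),
            abs(rowSums(fld$s * fld$n)))
  expect_lt(max(dots), 1e-8)
  dets <- rowSums(fld$f * lapwsim:::.cross3(fld$s, fld$n))
  expect_lt(max(abs(dets - 1)), 1e-8)
  # linear transmural interpolation of the in-plane angle
  ang <- atan2(fld$f[, 2], fld$f[, 1]) * 180 / pi
  expect_equal(ang, -30 + fld$depth * 60, tolerance = 1e-6)
  flat <- volume_mesh(mesh$vertices, mesh$tets)   # no transmural field
  expect_error(template_field(flat), "transmural")
})

test_that("fiber mapping by translation+scaling preserves directions", {
  mesh <- slab_coarse()
  fld <- template_field(mesh, -30, 30)
  same <- map_fibers(mesh, fld, mesh)
  expect_equal(same$f, fld$f, tolerance = 1e-12)
  scaled <- volume_mesh(mesh$vertices * 2, mesh$tets, mesh$subdomain, mesh$transmural)
  expect_equal(map_fibers(mesh, fld, scaled)$f, fld$f, tolerance = 1e-12)
  flatz <- mesh
  flatz$vertices[, 3] <- 0    # collapse one axis without re-validating
  expect_error(map_fibers(mesh, fld, flatz), "degenerate")
})

test_that("monodomain reduction is half the harmonic mean", {
  expect_equal(monodomain_sigma(1.74, 6.25), 1.3611, tolerance = 1e-4)
  expect_equal(monodomain_sigma(0.193, 2.36), 0.17841, tolerance = 1e-4)
  expect_equal(monodomain_sigma(3, 3), 1.5)
  expect_error(monodomain_sigma(0, 1), "positive")
  # harmonic-mean bound
  for (i in 1:20) {
    a <- runif(1, 0.01, 10); b <- runif(1, 0.01, 10)
    expect_lte(monodomain_sigma(a, b), min(a, b))
  }
})

test_that("conductivity tensors are transversely isotropic about the fiber", {
  sig <- conductivity_set()
  fx <- structure(list(f = rbind(c(1, 0, 0))), class = "lapw_fiber_field")
  Tx <- conductivity_tensor(fx, sig)[, , 1]
  expect_equal(Tx, diag(c(sig$sigma_l, sig$sigma_t, sig$sigma_t)), tolerance = 1e-12)
  iso <- conductivity_set(sigma_ti = 1.74, sigma_te = 6.25)   # sigma_l == sigma_t
  set.seed(1)
  f <- matrix(rnorm(30), 10); f <- f / sqrt(rowSums(f^2))
  fld <- structure(list(f = f), class = "lapw_fiber_field")
  Ti <- conductivity_tensor(fld, iso)
  for (e in 1:10)
    expect_equal(Ti[, , e], diag(rep(iso$sigma_t, 3)), tolerance = 1e-12)
  Ta <- conductivity_tensor(fld, sig)
  for (e in 1:10) {
    ev <- sort(eigen(Ta[, , e], symmetric = TRUE)$values)
    expect_equal(ev, sort(c(sig$sigma_l, sig$sigma_t, sig$sigma_t)),
                 tolerance = 1e-10)
  }
})

test_that("tensor fields transform covariantly under rotation", {
  sig <- conductivity_set()
  set.seed(2)
  f <- matrix(rnorm(15), 5); f <- f / sqrt(rowSums(f^2))
  fld <- structure(list(f = f), class = "lapw_fiber_field")
  Tn <- conductivity_tensor(fld, sig)
  th <- 0.7
  R <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  fldR <- structure(list(f = f %*% t(R)), class = "lapw_fiber_field")
  TR <- conductivity_tensor(fldR, sig)
  for (e in 1:5)
    expect_equal(TR[, , e], R %*% Tn[, , e] %*% t(R), tolerance = 1e-12)
})

test_that("CV measurement recovers an analytic planar activation field", {
  g <- as.matrix(expand.grid(x = seq(0, 40, 2), y = seq(0, 10, 2), z = 0))
  lats <- g[, 1] / 10 / 70 * 1000          # exact 70 cm/s plane wave
  cvm <- measure_cv(g, lats, which(g[, 1] <= 4), which(g[, 1] >= 36))
  expect_equal(cvm$cv, 70, tolerance = 1 / 70)
  expect_error(measure_cv(g, lats, which(g[, 1] <= 4), which(g[, 1] <= 4)),
               "coincide")
  expect_error(measure_cv(g, rev(lats), which(g[, 1] <= 4), which(g[, 1] >= 36)),
               "no later")
})

test_that("conductivity calibration converges under the square-root law", {
  # analytic slab stand-in: CV proportional to sqrt(sigma_l)
  fake_cv <- function(sig) 60 * sqrt(sig$sigma_l / monodomain_sigma(1.74, 6.25))
  cal <- calibrate_conductivity(fake_cv, conductivity_set(), cv_target = 60,
                                rel_tol = 0.02)
  expect_equal(attr(cal, "iterations"), 0)
  expect_equal(cal$K, 1)
  cal2 <- calibrate_conductivity(fake_cv, conductivity_set(), cv_target = 85,
                                 rel_tol = 0.02)
  expect_lt(abs(attr(cal2, "cv") - 85) / 85, 0.02)
  expect_equal(cal2$K, (85 / 60)^2, tolerance = 0.05)
  # all four compartment values share the calibration factor
  expect_equal(cal2$sigma_li / 1.74, cal2$sigma_te / 2.36, tolerance = 1e-12)
  expect_error(calibrate_conductivity(fake_cv, conductivity_set(), 0), "positive")
  expect_error(calibrate_conductivity(function(s) 60, conductivity_set(), 1000,
                                      rel_tol = 0.01, max_iter = 3),
               "converge")
})
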