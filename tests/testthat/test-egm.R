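# minimal hand-built simulation result: one tet, one emitting node
.point_source_fixture <- function(Q = 2, nt = 11) {
  verts <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))
  mesh <- volume_mesh(verts, matrix(1:4, 1))
  im <- matrix(0, 4, nt)
  im[1, ] <- Q
  res <- structure(list(im = im, times = seq(0, nt - 1),
                        active = 1:4, node_volume = c(0.3, 0.1, 0.1, 0.1),
                        config = list(chi = 1500)),
                   class = "lapw_sim_result")
  list(mesh = mesh, res = res)
}

test_that("a point source reproduces the closed-form potential", {
  fx <- .point_source_fixture(Q = 2)
  r_mm <- 10                               # electrode 10 mm above node 1
  tr <- forward_egm(fx$res, fx$mesh, c(0, 0, r_mm), sigma_b = 6.67)
  phi_exp <- 1500 * 2 * 0.3 / (4 * pi * 6.67 * (r_mm / 10))
  expect_equal(tr$phi, rep(phi_exp, 11), tolerance = 1e-12)
})

test_that("potential scales inversely with blood conductivity", {
  fx <- .point_source_fixture()
  a <- forward_egm(fx$res, fx$mesh, c(0, 0, 8), sigma_b = 6.67)
  b <- forward_egm(fx$res, fx$mesh, c(0, 0, 8), sigma_b = 13.34)
  expect_equal(b$phi, a$phi / 2, tolerance = 1e-12)
})

test_that("the forward map is linear in the membrane current", {
  fx1 <- .point_source_fixture(Q = 1)
  fx2 <- .point_source_fixture(Q = 3)
  fx2$res$im[2, ] <- -1.5
  fxs <- fx1
  fxs$res$im <- fx1$res$im + fx2$res$im
  el <- c(2, -1, 6)
  a <- forward_egm(fx1$res, fx1$mesh, el)
  b <- forward_egm(fx2$res, fx2$mesh, el)
  s <- forward_egm(fxs$res, fxs$mesh, el)
  expect_equal(s$phi, a$phi + b$phi, tolerance = 1e-10 * max(abs(s$phi)))
})

test_that("electrodes inside or touching the tissue are rejected", {
  fx <- .point_source_fixture()
  expect_error(forward_egm(fx$res, fx$mesh, c(0, 0, 0.05)), "inside")
})

test_that("a quiescent run produces a vanishing electrogram", {
  fx <- .point_source_fixture(Q = 0)
  tr <- forward_egm(fx$res, fx$mesh, c(0, 0, 5))
  expect_lt(max(abs(tr$phi)), 1e-6)
})

test_that("post-processing matches the clinical band and rate", {
  fs_in <- 2000
  t_ms <- seq(0, 500 - 0.5, by = 0.5)
  mk <- function(x) egm_set(t_ms, matrix(x), matrix(c(0, 0, 5), 1),
                            provenance = "simulated", sample_rate = fs_in)
  # DC is removed by the high-pass edge
  dc <- postprocess_egm(mk(rep(1, length(t_ms))))
  expect_lt(max(abs(dc$phi)), 0.01)
  # 100 Hz is in the passband
  s100 <- postprocess_egm(mk(sin(2 * pi * 100 * t_ms / 1000)))
  mid <- s100$phi[100:400, 1]
  expect_gt(max(mid), 0.9); expect_lt(max(mid), 1.001)
  # 400 Hz falls in the stopband
  s400 <- postprocess_egm(mk(sin(2 * pi * 400 * t_ms / 1000)))
  expect_lt(max(abs(s400$phi[100:400, 1])), 0.2)
  # decimation to 1 kHz
  expect_equal(s100$sample_rate, 1000)
  expect_equal(nrow(s100$phi), length(t_ms) / 2)
  expect_error(postprocess_egm(mk(rep(0, length(t_ms))), fs_out = 1000,
                               band = c(2, 1500)), "band")
})

test_that("a slab wavefront yields a biphasic EGM that decays with standoff", {
  res <- slab_healthy_result()
  mesh <- slab_coarse()
  p2p <- vapply(c(1, 2, 4), function(s) {
    tr <- forward_egm(res, mesh, c(10, 10, 2.3 + s), sigma_b = 6.67)
    diff(range(tr$phi))
  }, 1)
  expect_true(all(diff(p2p) < 0))          # monotone decay with distance
  raw <- forward_egm_set(res, mesh, rbind(c(10, 10, 4.3)), sigma_b = 6.67)
  pp <- postprocess_egm(raw)
  phi <- pp$phi[, 1]
  # dominant positive peak strictly before the dominant negative peak
  expect_lt(which.max(phi), which.min(phi))
  expect_equal(count_deflections(phi, pp$time, prominence_frac = 0.25), 2L)
})
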