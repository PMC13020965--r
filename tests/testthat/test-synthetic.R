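test_that("noiseless flat sheet is a regular grid with exact spacing", {
  pc <- make_sheet_pcd(sheet_spec(20, 20, point_spacing = 1))
  expect_equal(nrow(pc$points), 441)
  d <- as.matrix(dist(pc$points)); diag(d) <- Inf
  expect_equal(mean(apply(d, 1, min)), 1, tolerance = 1e-12)
})

test_that("sheet generation is deterministic per seed", {
  spec <- sheet_spec(15, 10, point_spacing = 1, positional_noise_sd = 0.2, seed = 42)
  expect_identical(make_sheet_pcd(spec)$points, make_sheet_pcd(spec)$points)
  spec2 <- sheet_spec(15, 10, point_spacing = 1, positional_noise_sd = 0.2, seed = 43)
  expect_false(identical(make_sheet_pcd(spec)$points, make_sheet_pcd(spec2)$points))
})

test_that("curved sheets lie exactly on the requested cylinder", {
  pc <- make_sheet_pcd(sheet_spec(20, 20, curvature_radius = 50, point_spacing = 1))
  # cylinder axis parallel to y through (x = 10, z = 50)
  r <- sqrt((pc$points[, 1] - 10)^2 + (pc$points[, 3] - 50)^2)
  expect_lt(max(abs(r - 50)), 1e-6)
})

test_that("sheet spec rejects invalid geometry", {
  expect_error(sheet_spec(-1, 10), "extents")
  expect_error(sheet_spec(10, 10, point_spacing = 0), "spacing")
  expect_error(sheet_spec(10, 10, positional_noise_sd = -1), "noise")
})

test_that("electrode grids sit standoff mm along the outward normal", {
  surf <- reconstruct_surface(make_sheet_pcd(sheet_spec(20, 20, point_spacing = 1)))
  el <- make_electrode_grid(surf, 5, standoff = 1)
  expect_equal(nrow(el), 25)                      # floor(20/5)+1 per axis
  expect_equal(unname(el[, 3]), rep(1, 25))       # flat sheet at z = 0
  expect_error(make_electrode_grid(surf, 5, standoff = 0), "standoff")
  expect_error(make_electrode_grid(surf, 50, standoff = 1), "extent")
})

test_that("pseudo-recordings without noise are identical up to time shifts", {
  el <- cbind(seq(0, 40, 10), 0, 2)
  spec <- pseudo_recording_spec(cv = 100, amplitude_sd = 0, jitter_sd = 0,
                                fractionation_probability = 0, duration = 140)
  set <- make_recorded_egm_set(el, spec)
  cons <- attr(set, "construction")
  # LAT spread = 40 mm / 100 cm/s = 40 ms
  expect_equal(diff(range(cons$lat)), 40)
  # shifting trace i by its LAT difference reproduces trace 1
  dt <- 1000 / spec$sample_rate
  for (i in 2:5) {
    shift <- round((cons$lat[i] - cons$lat[1]) / dt)
    n <- length(set$time)
    expect_equal(set$phi[seq_len(n - shift), 1],
                 set$phi[(shift + 1):n, i], tolerance = 1e-12)
  }
})

test_that("fractionation adds exactly the configured number of deflections", {
  el <- cbind(seq(0, 20, 5), 0, 2)
  spec <- pseudo_recording_spec(fractionation_probability = 1,
                                extra_deflection_count_range = c(2, 2),
                                amplitude_sd = 0, jitter_sd = 0)
  set <- make_recorded_egm_set(el, spec)
  cons <- attr(set, "construction")
  expect_true(all(cons$deflection_count == 4L))   # biphasic base 2 + 2
  for (i in seq_len(ncol(set$phi)))
    expect_equal(count_deflections(set$phi[, i], set$time), 4L)
})

test_that("pseudo-recording generation is deterministic and validates duration", {
  el <- cbind(seq(0, 20, 5), 0, 2)
  spec <- pseudo_recording_spec(amplitude_sd = 0.5, jitter_sd = 1,
                                fractionation_probability = 0.5, seed = 9)
  expect_identical(make_recorded_egm_set(el, spec)$phi,
                   make_recorded_egm_set(el, spec)$phi)
  short <- pseudo_recording_spec(cv = 10, duration = 30)
  expect_error(make_recorded_egm_set(cbind(seq(0, 40, 10), 0, 2), short),
               "duration")
})

test_that("construction LATs are recovered by detect_lat to one sample", {
  el <- cbind(runif(30, 0, 30), runif(30, 0, 30), 2)
  spec <- pseudo_recording_spec(amplitude_sd = 0.3, jitter_sd = 0.5, seed = 4)
  set <- make_recorded_egm_set(el, spec)
  cons <- attr(set, "construction")
  got <- vapply(seq_len(30), function(i) detect_lat(set$phi[, i], set$time), 1)
  expect_true(all(abs(got - cons$lat) <= 1))
})

test_that("configured conduction velocity is recovered from the pseudo LAT field", {
  el <- as.matrix(expand.grid(x = seq(0, 40, 4), y = seq(0, 20, 4)))
  el <- cbind(el, 2)
  spec <- pseudo_recording_spec(cv = 70, amplitude_sd = 0, jitter_sd = 0)
  set <- make_recorded_egm_set(el, spec)
  lats <- vapply(seq_len(ncol(set$phi)), function(i)
    detect_lat(set$phi[, i], set$time), 1)
  cvm <- measure_cv(el, lats, which(el[, 1] <= 4), which(el[, 1] >= 36))
  expect_lt(abs(cvm$cv - 70) / 70, 0.05)
})
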