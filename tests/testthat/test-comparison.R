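test_that("Cohen's d handles degenerate and invariance cases", {
  expect_equal(cohens_d(group_summary(5, 2, 100), group_summary(5, 3, 100))$d, 0)
  expect_error(cohens_d(group_summary(1, 0, 10), group_summary(2, 0, 10)), "pooled")
  # invariance under a common affine transform of the raw data
  set.seed(3)
  a <- rnorm(50, 2, 1); b <- rnorm(50, 3, 2)
  d0 <- cohens_d(a, b)$d
  d1 <- cohens_d(4 * a - 7, 4 * b - 7)$d
  expect_equal(d1, d0, tolerance = 1e-12)
  expect_equal(cohens_d(a, b)$d_signed, -cohens_d(b, a)$d_signed)
  expect_equal(cohens_d(group_summary(1, 1, 10), group_summary(1.05, 1, 10))$band,
               "negligible")
})

test_that("percent errors follow the definition", {
  f <- data.frame(peak_to_peak = c(2, 2, 2), deflection_count = c(4, 4, 4),
                  egm_duration = c(100, 100, 100), lat = c(50, 50, 50))
  e0 <- error_metrics(f, f)
  expect_true(all(e0$mean == 0) && all(e0$sd == 0))
  g <- f
  g$peak_to_peak <- c(2.2, 2.4, 2.6)   # 10, 20, 30 percent errors
  e1 <- error_metrics(f, g)
  row <- e1[e1$feature == "peak_to_peak", ]
  expect_equal(row$mean, 20)
  expect_equal(row$sd, 10)
  f2 <- f; f2$lat <- c(0, 50, 50)      # zero recorded value excluded
  e2 <- error_metrics(f2, g)
  expect_equal(e2[e2$feature == "lat", "n_excluded"], 1)
  expect_equal(error_metrics(data.frame(peak_to_peak = 2, deflection_count = 4,
                                        egm_duration = 100, lat = 50),
                             data.frame(peak_to_peak = 3, deflection_count = 4,
                                        egm_duration = 100, lat = 50))$mean[1], 50)
})

test_that("correlation metrics detect identity, delay and inversion", {
  tr <- sin(2 * pi * seq(0, 1, length.out = 140) * 3) * exp(-seq(0, 5, length.out = 140))
  self <- correlation_metrics(tr, tr)
  expect_equal(self$pearson_r, 1)
  expect_equal(self$xcorr_peak, 1, tolerance = 1e-12)
  expect_equal(self$xcorr_lag, 0)
  shifted <- c(rep(0, 20), tr[1:120])
  del <- correlation_metrics(c(tr[1:120], rep(0, 20)), shifted)
  expect_lt(del$pearson_r, 1)
  expect_equal(del$xcorr_peak, 1, tolerance = 1e-6)
  expect_equal(abs(del$xcorr_lag), 20)
  expect_equal(correlation_metrics(tr, -tr)$pearson_r, -1)
  expect_error(correlation_metrics(tr, rep(1, 140)), "variance")
})

test_that("the biorthogonal bank is linear with perfect reconstruction", {
  expect_true(all(wavelet_detail_coeffs(rep(0, 140)) == 0))
  set.seed(9)
  x <- rnorm(140); y <- rnorm(140)
  cx <- wavelet_detail_coeffs(x)
  expect_equal(wavelet_detail_coeffs(3.5 * x), 3.5 * cx, tolerance = 1e-12)
  expect_equal(wavelet_detail_coeffs(x + y),
               cx + wavelet_detail_coeffs(y), tolerance = 1e-10)
  dec <- wavelet_decompose(x, 4)
  expect_equal(wavelet_reconstruct(dec, 140), x, tolerance = 1e-8)
  expect_error(wavelet_decompose(rnorm(5), 4), "short")
})

test_that("PCA embedding retains components to the variance target", {
  set.seed(4)
  line <- outer(rnorm(60), c(1, 2, -1, 0.5)) + matrix(rnorm(240, sd = 1e-4), 60)
  emb1 <- pca_embed(line)
  expect_equal(emb1$k, 1)
  X <- matrix(rnorm(60 * 20), 60)
  emb <- pca_embed(X, 0.9)
  G <- t(emb$components) %*% emb$components
  expect_equal(G, diag(emb$k), tolerance = 1e-10, ignore_attr = TRUE)
  full <- prcomp(X)
  expect_equal(sum(full$sdev^2), sum(apply(X, 2, var)), tolerance = 1e-10)
  # projection consistency
  expect_equal(project_scores(X, emb), emb$scores, tolerance = 1e-10,
               ignore_attr = TRUE)
  expect_equal(as.numeric(project_scores(rbind(emb$mean), emb)),
               rep(0, emb$k), tolerance = 1e-10)
  probe <- rbind(emb$mean + emb$components[, 1])
  expect_equal(as.numeric(project_scores(probe, emb)),
               c(1, rep(0, emb$k - 1)), tolerance = 1e-10)
  expect_error(pca_embed(X[1, , drop = FALSE]), "at least 2")
})

test_that("seeded k-means recovers separated blobs deterministically", {
  set.seed(6)
  X <- rbind(matrix(rnorm(60, 0), ncol = 2), matrix(rnorm(60, 8), ncol = 2),
             cbind(rnorm(30, 16), rnorm(30, 0)))
  truth <- rep(1:3, each = 30)
  cl <- kmeans_cluster(X, k = 3, seed = 2)
  expect_identical(cl$labels, kmeans_cluster(X, k = 3, seed = 2)$labels)
  # partition equals blob membership up to relabeling
  tab <- table(truth, cl$labels)
  expect_equal(sum(apply(tab, 1, max)), 90)
  cln <- kmeans_cluster(X, k = nrow(X), seed = 1)
  expect_equal(sum(cln$withinss), 0)
  expect_error(kmeans_cluster(X, k = 0), "k must")
  expect_error(kmeans_cluster(X[1:2, ], k = 5), "exceeds")
})

test_that("centroid distances count cluster disagreements exactly", {
  centroids <- rbind(c(0, 0), c(10, 0), c(0, 10))
  rec_labels <- c(1, 1, 2, 3)
  sim <- rbind(c(0.1, 0), c(9.9, 0), c(10.2, 0), c(0, 9.8))
  cd <- centroid_distances(sim, rec_labels, centroids)
  # point 2 sits at cluster 2 while its recorded partner is in cluster 1
  expect_equal(cd$percent_different, 25)
  same <- centroid_distances(rbind(c(0, 0), c(10, 0), c(0, 10)), c(1, 2, 3), centroids)
  expect_equal(same$percent_different, 0)
  expect_equal(same$common, same$closest)
  expect_error(centroid_distances(sim[0, ], integer(0), centroids), "empty")
})

test_that("isochrone mapping assigns nearest-electrode LATs with shared bins", {
  pts <- as.matrix(expand.grid(x = seq(0, 20, 1), y = seq(0, 20, 1)))
  pts <- cbind(pts, 0)
  el <- rbind(c(5, 10, 2), c(15, 10, 2))
  iso <- isochrone_map(pts, el, lats = c(10, 30), n_bins = 2)
  on_el <- which(pts[, 1] == 5 & pts[, 2] == 10)
  expect_equal(iso$lat[on_el], 10)
  # equidistant points go to the lower-index electrode
  mid <- which(pts[, 1] == 10)
  expect_true(all(iso$electrode[mid] == 1))
  # planar LAT field gives bands split along x
  expect_true(all(iso$bin[pts[, 1] < 10] == 1))
  expect_true(all(iso$bin[pts[, 1] > 10] == 2))
  expect_error(isochrone_map(pts, el, lats = c(NA, NA)), "finite")
})

test_that("the ANOVA/Tukey convenience reports group effects", {
  set.seed(12)
  vals <- c(rnorm(30, 0), rnorm(30, 1), rnorm(30, 4))
  grp <- rep(c("d10", "d35", "d60"), each = 30)
  a <- anova_tukey(vals, grp)
  expect_gt(a$F, 10)
  expect_lt(a$p, 1e-6)
  expect_equal(nrow(a$tukey), 3)
})
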