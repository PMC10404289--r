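gaussian_blobs <- function(k = 3, per = 40, sep = 8, d = 2, seed = 1) {
  set.seed(seed)
  centers <- matrix(rnorm(k * d), k, d) * sep
  x <- do.call(rbind, lapply(seq_len(k), function(i) {
    sweep(matrix(rnorm(per * d, sd = 0.5), per, d), 2, centers[i, ], "+")
  }))
  ids <- tibble::tibble(core_id = "c", patient_id = "p",
                        row = seq_len(k * per), col = 1L)
  list(fm = feature_matrix(ids, x, "blobs"), centers = centers,
       truth = rep(seq_len(k), each = per))
}

test_that("silhouette selection recovers the blob count and respects ties/edges", {
  b <- gaussian_blobs(k = 3, per = 40, seed = 3)
  expect_equal(select_k_silhouette(b$fm, 2:6, seed = 1), 3)
  # duplicating every point leaves the selection unchanged
  dup <- feature_matrix(dplyr::bind_rows(b$fm$ids, b$fm$ids),
                        rbind(b$fm$x, b$fm$x), "blobs")
  expect_equal(select_k_silhouette(dup, 2:6, seed = 1), 3)
  # singleton range short-circuits
  expect_equal(select_k_silhouette(b$fm, 4, seed = 1), 4)
  tiny <- feature_matrix(b$fm$ids[1:2, ], b$fm$x[1:2, , drop = FALSE], "blobs")
  expect_error(select_k_silhouette(tiny, 2:3), class = "renograph_insufficient")
})

test_that("k-means recovers structure and is deterministic", {
  b <- gaussian_blobs(k = 2, per = 60, sep = 10, seed = 5)
  m1 <- fit_kmeans(b$fm, 2, seed = 9)
  m2 <- fit_kmeans(b$fm, 2, seed = 9)
  expect_identical(m1$centroids, m2$centroids)
  # centroids near the true blob means (3 SEM of a 0.5-sd component)
  sem <- 0.5 / sqrt(60)
  dmat <- as.matrix(dist(rbind(m1$centroids, b$centers)))[1:2, 3:4]
  expect_true(all(apply(dmat, 1, min) < 3 * sem * sqrt(2) + 0.05))

  # K points in K clusters: zero inertia, each point its own centroid
  five <- feature_matrix(b$fm$ids[1:5, ],
                         matrix(c(0, 10, 20, 30, 40, 0, 0, 0, 0, 0), 5, 2),
                         "blobs")
  mk <- fit_kmeans(five, 5, seed = 1)
  expect_equal(mk$inertia, 0)
  expect_setequal(mk$centroids[, 1], c(0, 10, 20, 30, 40))
  expect_error(fit_kmeans(five, 6, seed = 1), class = "renograph_invalid")
})

test_that("assignment equals the brute-force nearest-centroid scan", {
  set.seed(11)
  b <- gaussian_blobs(k = 3, per = 30, seed = 7)
  model <- fit_kmeans(b$fm, 3, seed = 2)
  asg <- assign_clusters(b$fm, model)
  brute <- apply(b$fm$x, 1, function(p) {
    which.min(colSums((t(model$centroids) - p)^2))
  })
  expect_equal(asg$cluster, unname(brute))
  expect_true(all(asg$distances >= 0))
  # stored index minimizes the stored distances
  expect_equal(asg$cluster, unname(apply(asg$distances, 1, which.min)))

  # exact centroid gets distance zero; equidistant ties go to the lower index
  probe <- feature_matrix(b$fm$ids[1:2, ],
                          rbind(model$centroids[2, ],
                                (model$centroids[1, ] + model$centroids[3, ]) / 2),
                          "blobs")
  pasg <- assign_clusters(probe, model)
  expect_equal(pasg$cluster[1], 2)
  expect_equal(pasg$distances[1, 2], 0)
  two <- matrix(c(0, 0, 4, 0), 2, 2, byrow = TRUE)
  mod2 <- structure(list(k = 2L, centroids = two,
                         mds_order = 1:2, mds_coords = matrix(0, 2, 2),
                         palette = c("#000000", "#FFFFFF")),
                    class = "cluster_model")
  mid <- feature_matrix(b$fm$ids[1, ], matrix(c(2, 0), 1, 2), "blobs")
  expect_equal(assign_clusters(mid, mod2)$cluster, 1L)

  wrong <- feature_matrix(b$fm$ids[1, ], matrix(0, 1, 5), "blobs")
  expect_error(assign_clusters(wrong, model), class = "renograph_shape")
})

test_that("classical MDS ordering is exact, invariant and sign-fixed", {
  # collinear centroids at 0, 1, 3 along a line embed exactly
  cents <- matrix(c(0, 1, 3, 0, 0, 0), 3, 2)
  mds <- order_clusters_mds(cents, m = 2)
  d1 <- as.matrix(dist(mds$mds_coords[, 1]))
  expect_equal(d1, as.matrix(dist(cents)), tolerance = 1e-9,
               ignore_attr = TRUE)
  # lowest-index extreme sits at the left end
  expect_equal(mds$mds_order[1], 1)

  # double-centring oracle: full-rank embedding reproduces all distances
  set.seed(13)
  c4 <- matrix(rnorm(4 * 3), 4, 3)
  full <- order_clusters_mds(c4, m = 3)
  expect_equal(as.matrix(dist(full$mds_coords)), as.matrix(dist(c4)),
               tolerance = 1e-6, ignore_attr = TRUE)

  # permuting centroid rows permutes but does not reorder the clusters —
  # up to a whole-axis reflection, since the sign convention is anchored to
  # the (permutation-dependent) original indices of the extreme clusters
  perm <- c(3L, 1L, 4L, 2L)
  permuted <- order_clusters_mds(c4[perm, ], m = 3)
  back <- perm[permuted$mds_order]
  expect_true(identical(back, full$mds_order) ||
                identical(back, rev(full$mds_order)))

  expect_error(order_clusters_mds(matrix(1, 3, 2)),
               class = "renograph_degenerate")
})

test_that("case histograms respect MDS order, normalization and ground truth", {
  ps <- pattern_feature_set(k = 3, per = 20, seed = 6)
  model <- fit_kmeans(ps$fm, 3, seed = 4)
  # relabel ids: patient A gets 50% pattern 1, 30% pattern 2, 20% pattern 3
  pick <- c(which(ps$truth == 1)[1:10], which(ps$truth == 2)[1:6],
            which(ps$truth == 3)[1:4])
  sub <- feature_matrix(ps$fm$ids[pick, ], ps$fm$x[pick, , drop = FALSE],
                        "texture")
  sub$ids$patient_id <- "A"
  asg <- assign_clusters(sub, model)
  h <- case_histogram(asg, model)
  f <- as.numeric(h[1, paste0("f", 1:3)])
  expect_equal(sum(f), 1, tolerance = 1e-9)
  expect_setequal(round(f, 10), c(0.5, 0.3, 0.2))
  expect_equal(h$total_patches, 20L)

  # a patient concentrated in one cluster puts mass 1 at its ordered bin
  solo <- feature_matrix(ps$fm$ids[ps$truth == 2, ],
                         ps$fm$x[ps$truth == 2, , drop = FALSE], "texture")
  solo$ids$patient_id <- "B"
  asg_b <- assign_clusters(solo, model)
  hb <- case_histogram(asg_b, model)
  fb <- as.numeric(hb[1, paste0("f", 1:3)])
  expect_equal(sort(fb), c(0, 0, 1))
  pos <- which(model$mds_order == asg_b$cluster[1])
  expect_equal(fb[pos], 1)

  # counts mode sums to the number of assigned patches
  hc <- case_histogram(asg, model, mode = "counts")
  expect_equal(sum(as.numeric(hc[1, paste0("f", 1:3)])), 20)
})

test_that("quartic trend recovery matches exact and normal-equation oracles", {
  x <- 1:9
  truth <- c(1, -2, 0, 3, 5)
  y <- truth[1] * x^4 + truth[2] * x^3 + truth[3] * x^2 + truth[4] * x + truth[5]
  expect_equal(unname(fit_poly4(y)), truth, tolerance = 1e-8)

  const <- fit_poly4(rep(0.3, 9))
  expect_equal(unname(const[1:4]), rep(0, 4), tolerance = 1e-10)
  expect_equal(unname(const[5]), 0.3, tolerance = 1e-10)

  set.seed(17)
  r <- runif(9)
  v <- cbind(x^4, x^3, x^2, x, 1)
  oracle <- solve(t(v) %*% v, t(v) %*% r)
  expect_equal(unname(fit_poly4(r)), as.numeric(oracle), tolerance = 1e-8)

  expect_error(fit_poly4(runif(4)), class = "renograph_underdetermined")
})

test_that("clustering pipeline recovers planted texture patterns", {
  ps <- pattern_feature_set(k = 4, per = 40, seed = 8)
  expect_equal(select_k_silhouette(ps$fm, 2:7, seed = 3), 4)
  model <- fit_kmeans(ps$fm, 4, seed = 5)
  asg <- assign_clusters(ps$fm, model)
  expect_gte(adjusted_rand(asg$cluster, ps$truth), 0.9)
})
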