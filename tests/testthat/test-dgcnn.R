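test_that("graph convolution follows the row-normalized propagation rule", {
  # single node with identity weights passes features through
  g1 <- lattice_graph(1, 1, feat = matrix(c(0.3, -0.7), 1, 2))
  out <- graph_conv_forward(g1, diag(2), activation = identity)
  expect_equal(out, matrix(c(0.3, -0.7), 1, 2))

  # two connected identical-feature nodes stay identical (symmetry)
  g2 <- lattice_graph(1, 2, feat = matrix(c(0.5, 0.5, -1, -1), 2, 2))
  out2 <- graph_conv_forward(g2, diag(2))
  expect_equal(out2[1, ], out2[2, ])

  # 3-node path with hand-set 1-D features and 1x1 weight
  g3 <- lattice_graph(1, 3, feat = matrix(c(1, 2, 4), 3, 1))
  w <- matrix(2, 1, 1)
  # P = D^-1 (A+I); rows: (1+2)/2, (1+2+4)/3, (2+4)/2
  hand <- tanh(matrix(c(3 / 2, 7 / 3, 6 / 2), 3, 1) * 2)
  expect_equal(graph_conv_forward(g3, w), hand)

  expect_error(graph_conv_forward(g3, diag(2)), class = "renograph_shape")
})

test_that("SortPooling sorts, pads and matches a brute-force oracle", {
  z <- matrix(c(0.1, 0.9, 0.5,
                1.0, 2.0, 3.0), 3, 2)
  sp <- sort_pooling(z, 3)
  expect_equal(sp$idx, c(3L, 2L, 1L))          # descending last channel
  expect_equal(sp$s, z[3:1, ])

  # short graphs are zero-padded at the bottom
  sp2 <- sort_pooling(z, 5)
  expect_equal(sp2$n_real, 3)
  expect_equal(sp2$s[4:5, ], matrix(0, 2, 2))

  # ties on the last channel fall back to the next channel, then row order
  zt <- matrix(c(0.2, 0.8, 0.8, 0.5,
                 1, 1, 1, 0), 4, 2)
  spt <- sort_pooling(zt, 4)
  expect_equal(spt$idx, c(2L, 3L, 1L, 4L))

  # brute-force reversed-channel lexicographic top-k
  set.seed(29)
  zr <- matrix(rnorm(40), 10, 4)
  spr <- sort_pooling(zr, 6)
  brute <- order(-zr[, 4], -zr[, 3], -zr[, 2], -zr[, 1])[1:6]
  expect_equal(spr$idx, brute)

  expect_error(sort_pooling(zr, 0), class = "renograph_config")
})

test_that("backpropagation matches finite differences", {
  set.seed(31)
  g <- lattice_graph(2, 3, feat = matrix(rnorm(12), 6, 2), label = 1L)
  cfg <- dgcnn_config(conv_channels = c(4, 3, 3, 1), conv1d_channels = c(2, 3),
                      conv2_width = 2, dense_units = 5, dropout = 0,
                      sortpool_k = 5, epochs = 1)
  params <- renograph:::dgcnn_init(cfg, 2, 5)
  # move biases off the ReLU kink so central differences are well-defined
  params$b1 <- params$b1 + 0.1
  params$b2 <- params$b2 + 0.1
  params$bd <- params$bd + 0.1
  params$bo <- 0.05
  fw <- renograph:::dgcnn_forward(g, params, cfg, keep = TRUE)
  gr <- renograph:::dgcnn_backward(fw, params, cfg, 1)
  loss_at <- function(p) {
    s <- renograph:::dgcnn_forward(g, p, cfg)
    -log(s)
  }
  eps <- 1e-6
  for (nm in c("Wg1", "Wg2", "Wg4", "W1", "W2", "Wd", "Wo", "b1", "b2", "bd")) {
    idx <- seq_len(min(3, length(params[[nm]])))
    for (i in idx) {
      p2 <- params
      p2[[nm]][i] <- p2[[nm]][i] + eps
      attr(p2, "shape") <- attr(params, "shape")
      up <- loss_at(p2)
      p2[[nm]][i] <- p2[[nm]][i] - 2 * eps
      dn <- loss_at(p2)
      expect_equal(gr[[nm]][i], (up - dn) / (2 * eps), tolerance = 1e-4)
    }
  }
})

test_that("the class score is invariant to node permutation and padding", {
  set.seed(37)
  coh <- separable_graph_cohort(12, nr = 4, nc = 4, seed = 5)
  cfg <- dgcnn_config(conv_channels = c(8, 8, 8, 1), conv1d_channels = c(4, 6),
                      dense_units = 16, sortpool_k = 12, epochs = 3,
                      learning_rate = 1e-3, seed = 2)
  model <- renograph:::dgcnn_fit(coh$graphs, coh$labels$label, cfg, seed = 3)
  g <- coh$graphs[[1]]
  s0 <- predict_core(model, g, score = TRUE)

  # permute node order (remapping edges accordingly)
  perm <- sample(nrow(g$nodes))
  inv <- order(perm)
  gp <- g
  gp$nodes <- g$nodes[perm, ]
  gp$edges <- matrix(inv[g$edges], ncol = 2)
  gp$edges <- cbind(pmin(gp$edges[, 1], gp$edges[, 2]),
                    pmax(gp$edges[, 1], gp$edges[, 2]))
  s1 <- predict_core(model, gp, score = TRUE)
  expect_lt(abs(s0 - s1), 1e-5)

  # phantom isolated zero-feature rows beyond sortpool_k never change the
  # output when their sort keys are strictly smallest: with positive node
  # features and positive graph-conv weights every real embedding is
  # positive while an isolated zero row stays exactly zero
  gpos <- g
  gpos$nodes$x1 <- abs(gpos$nodes$x1) + 0.1
  gpos$nodes$x2 <- abs(gpos$nodes$x2) + 0.1
  pos_model <- model
  for (nm in c("Wg1", "Wg2", "Wg3", "Wg4")) {
    pos_model$params[[nm]] <- abs(pos_model$params[[nm]])
  }
  sp0 <- predict_core(pos_model, gpos, score = TRUE)
  gpad <- gpos
  gpad$nodes <- dplyr::bind_rows(
    gpos$nodes,
    tibble::tibble(row = 99L, col = 99L, cluster = 1L, x1 = 0, x2 = 0))
  s2 <- predict_core(pos_model, gpad, score = TRUE)
  expect_lt(abs(sp0 - s2), 1e-5)

  # zeroed output layer scores exactly 0.5 -> class +1 by convention
  zeroed <- model
  zeroed$params$Wo[] <- 0
  zeroed$params$bo <- 0
  expect_equal(predict_core(zeroed, g, score = TRUE), 0.5)
  expect_equal(predict_core(zeroed, g), 1L)

  wrongdim <- g
  wrongdim$nodes$x3 <- 1
  expect_error(predict_core(model, wrongdim), class = "renograph_shape")
})

test_that("stratified fold plans keep patients intact and classes balanced", {
  labs <- tibble::tibble(patient_id = sprintf("p%02d", 1:20),
                         label = rep(c(1L, -1L), c(12, 8)))
  plan <- make_fold_plan(labs, n_folds = 3, seed = 4)
  a <- plan$assignment
  expect_setequal(a$patient_id, labs$patient_id)
  expect_true(all(table(a$patient_id) == 1))
  per_fold <- table(a$fold, a$label)
  expect_true(all(abs(per_fold[, "1"] - 4) <= 1))
  expect_true(all(abs(per_fold[, "-1"] - 8 / 3) <= 1))
})

test_that("cross-validated training learns a separable cohort and is seeded", {
  coh <- separable_graph_cohort(36, nr = 5, nc = 5, seed = 11)
  plan <- make_fold_plan(coh$labels, seed = 2)
  cfg <- dgcnn_config(conv_channels = c(8, 8, 8, 1), conv1d_channels = c(4, 6),
                      dense_units = 16, epochs = 15, learning_rate = 2e-3,
                      seed = 6)
  cv <- train_dgcnn(coh$graphs, plan, cfg)
  truth <- setNames(coh$labels$label, coh$labels$patient_id)
  acc <- mean(cv$oof$pred == truth[cv$oof$patient_id])
  expect_gte(acc, 0.9)
  # every core exactly one out-of-fold prediction
  expect_setequal(cv$oof$core_id, vapply(coh$graphs, `[[`, "", "core_id"))
  expect_false(any(duplicated(cv$oof$core_id)))
  # loss decreases over the first epochs on a separable cohort
  h <- cv$models[[1]]$history
  expect_lt(h[5], h[1])
  # determinism: the same seed reproduces folds and predictions exactly
  cv2 <- train_dgcnn(coh$graphs, plan, cfg)
  expect_identical(cv$oof, cv2$oof)

  # single-class training folds are refused with the fold named
  bad_plan <- plan
  bad_plan$assignment$label <- 1L
  lab1 <- coh$labels$patient_id[coh$labels$label == 1L]
  graphs1 <- coh$graphs[vapply(coh$graphs, `[[`, "", "patient_id") %in% lab1]
  expect_error(train_dgcnn(graphs1, plan, cfg),
               class = "renograph_stratification")
})

test_that("label-shuffled training stays at chance", {
  set.seed(41)
  coh <- separable_graph_cohort(36, nr = 4, nc = 4, seed = 13)
  shuffled <- coh$labels
  shuffled$label <- sample(shuffled$label)
  graphs <- lapply(coh$graphs, function(g) {
    g$label <- shuffled$label[match(g$patient_id, shuffled$patient_id)]
    g
  })
  plan <- make_fold_plan(shuffled, seed = 3)
  cfg <- dgcnn_config(conv_channels = c(8, 8, 8, 1), conv1d_channels = c(4, 6),
                      dense_units = 16, epochs = 10, learning_rate = 2e-3,
                      seed = 8)
  cv <- train_dgcnn(graphs, plan, cfg)
  truth <- setNames(shuffled$label, shuffled$patient_id)
  acc <- mean(cv$oof$pred == truth[cv$oof$patient_id])
  expect_lt(abs(acc - 0.5), 3 * sqrt(0.25 / 36))
})
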