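#' Deep graph CNN configuration
#'
#' Topology: four graph convolution layers, SortPooling, two 1-D
#' convolutions separated by width-2 max pooling, and a fully connected
#' layer with dropout feeding a sigmoid output. Defaults follow the original
#' deep graph CNN recipe; every field is overridable.
#'
#' @param conv_channels output channels of the four graph conv layers.
#' @param sortpool_k number of nodes kept by SortPooling, or `NULL` to set k
#'   at train time so that ~60\% of training graphs have at least k nodes
#'   (never below 10 so the convolution stack stays well-formed).
#' @param conv1d_channels filters of the two 1-D conv layers.
#' @param conv2_width width of the second 1-D convolution (the first has
#'   width and stride equal to the total graph-conv channel count).
#' @param dense_units fully connected layer width.
#' @param dropout dropout probability on the dense layer, in `[0, 1)`.
#' @param learning_rate Adam step size.
#' @param epochs training epochs (>= 1).
#' @param batch_size kept for interface completeness; updates are per-graph.
#' @param seed integer seed driving initialization, shuffling and dropout.
#' @return a `dgcnn_config` object.
#' @export
dgcnn_config <- function(conv_channels = c(32L, 32L, 32L, 1L),
                         sortpool_k = NULL,
                         conv1d_channels = c(16L, 32L),
                         conv2_width = 5L,
                         dense_units = 128L,
                         dropout = 0.5,
                         learning_rate = 1e-4,
                         epochs = 100L,
                         batch_size = 1L,
                         seed = 1L) {
  assert_that(length(conv_channels) == 4, "exactly four graph conv layers")
  assert_that(is.null(sortpool_k) || sortpool_k >= 1, "sortpool_k must be >= 1",
              "renograph_config")
  assert_that(epochs >= 1, "epochs must be >= 1")
  assert_that(dropout >= 0 && dropout < 1, "dropout must be in [0, 1)")
  structure(
    list(conv_channels = as.integer(conv_channels),
         sortpool_k = if (is.null(sortpool_k)) NULL else as.integer(sortpool_k),
         conv1d_channels = as.integer(conv1d_channels),
         conv2_width = as.integer(conv2_width),
         dense_units = as.integer(dense_units),
         dropout = dropout, learning_rate = learning_rate,
         epochs = as.integer(epochs), batch_size = as.integer(batch_size),
         seed = as.integer(seed)),
    class = "dgcnn_config"
  )
}

# ---- graph propagation -----------------------------------------------------

# Per-graph propagation structure: degrees (with self-loop) and the
# bidirectional edge index used for neighbour sums.
graph_prop <- function(g) {
  n <- nrow(g$nodes)
  if (!is.null(g$edges) && nrow(g$edges) > 0) {
    ei <- c(g$edges[, 1], g$edges[, 2])
    ej <- c(g$edges[, 2], g$edges[, 1])
  } else {
    ei <- integer(0); ej <- integer(0)
  }
  list(n = n, ei = ei, ej = ej, deg = 1 + tabulate(ei, nbins = n))
}

# Sum of neighbour rows: NS[i, ] = sum_{j ~ i} X[j, ].
neighbour_sum <- function(pr, x) {
  ns <- matrix(0, pr$n, ncol(x))
  if (length(pr$ei) > 0) {
    agg <- rowsum(x[pr$ej, , drop = FALSE], pr$ei)
    ns[as.integer(rownames(agg)), ] <- agg
  }
  ns
}

# P X with P = D^{-1}(A + I): row-normalized propagation with self-loops,
# so isolated nodes (degree 1 via the self-loop) are well-defined.
prop_forward <- function(pr, x) (x + neighbour_sum(pr, x)) / pr$deg

# t(P) X, needed for backpropagation.
prop_backward <- function(pr, x) {
  xd <- x / pr$deg
  xd + neighbour_sum(pr, xd)
}

#' One graph convolution layer
#'
#' Computes `act(D^-1 (A + I) Z W)` — the deep graph CNN propagation rule —
#' for a single graph.
#'
#' @param graph a `core_graph`.
#' @param weights input-dim x output-dim weight matrix.
#' @param activation activation function (default [tanh]).
#' @param features optional node feature matrix overriding the graph's own.
#' @return n x output-dim node embedding matrix.
#' @export
graph_conv_forward <- function(graph, weights, activation = tanh,
                               features = NULL) {
  z <- features %||% graph_features(graph)
  if (ncol(z) != nrow(weights)) {
    stop_input(sprintf("node feature dim %d does not match weight rows %d",
                       ncol(z), nrow(weights)), "renograph_shape")
  }
  pr <- graph_prop(graph)
  activation(prop_forward(pr, z) %*% weights)
}

#' SortPooling
#'
#' Sorts node embeddings descending by the last channel (ties resolved by
#' the next channel leftwards, then by stable row order), keeps the top `k`
#' rows, and zero-pads graphs with fewer than `k` nodes.
#'
#' @param z n x c node embedding matrix.
#' @param k number of rows kept.
#' @return list: `s` (k x c matrix), `idx` (source row of each kept row;
#'   NA for padding), `n_real` (number of non-padded rows).
#' @export
sort_pooling <- function(z, k) {
  assert_that(k >= 1, "sortpool k must be >= 1", "renograph_config")
  assert_that(nrow(z) >= 1, "empty embedding matrix", "renograph_empty")
  n <- nrow(z); c <- ncol(z)
  keys <- c(lapply(rev(seq_len(c)), function(j) -z[, j]), list(seq_len(n)))
  ord <- do.call(order, keys)
  take <- ord[seq_len(min(k, n))]
  s <- matrix(0, k, c)
  s[seq_along(take), ] <- z[take, , drop = FALSE]
  list(s = s, idx = c(take, rep(NA_integer_, k - length(take))),
       n_real = length(take))
}

# ---- parameters ------------------------------------------------------------

glorot <- function(nin, nout) {
  s <- sqrt(6 / (nin + nout))
  matrix(stats::runif(nin * nout, -s, s), nin, nout)
}

# Initialize all parameter tensors for input dimension m and SortPool k.
dgcnn_init <- function(cfg, m, k) {
  ch <- cfg$conv_channels
  ctot <- sum(ch)
  f1 <- cfg$conv1d_channels[1]; f2 <- cfg$conv1d_channels[2]
  t2 <- k %/% 2L
  l2 <- t2 - cfg$conv2_width + 1L
  assert_that(l2 >= 1, "sortpool_k too small for the convolution stack",
              "renograph_config")
  dims <- c(m, ch)
  params <- list()
  for (t in 1:4) params[[paste0("Wg", t)]] <- glorot(dims[t], dims[t + 1])
  params$W1 <- glorot(ctot, f1); params$b1 <- rep(0, f1)
  params$W2 <- glorot(cfg$conv2_width * f1, f2); params$b2 <- rep(0, f2)
  params$Wd <- glorot(l2 * f2, cfg$dense_units); params$bd <- rep(0, cfg$dense_units)
  params$Wo <- glorot(cfg$dense_units, 1); params$bo <- 0
  attr(params, "shape") <- list(m = m, k = k, ctot = ctot, f1 = f1, f2 = f2,
                                t2 = t2, l2 = l2, w2 = cfg$conv2_width)
  params
}

relu <- function(x) pmax(x, 0)

# ---- forward / backward ----------------------------------------------------

# Full forward pass for one graph. Returns the sigmoid score and, when
# keep = TRUE, every intermediate needed by the backward pass.
dgcnn_forward <- function(g, params, cfg, drop_mask = NULL, keep = FALSE) {
  sh <- attr(params, "shape")
  z <- graph_features(g)
  if (ncol(z) != sh$m) {
    stop_input(sprintf("graph feature dim %d does not match model dim %d",
                       ncol(z), sh$m), "renograph_shape")
  }
  pr <- graph_prop(g)
  zs <- list(z); pzs <- list()
  for (t in 1:4) {
    pz <- prop_forward(pr, zs[[t]])
    pzs[[t]] <- pz
    zs[[t + 1]] <- tanh(pz %*% params[[paste0("Wg", t)]])
  }
  zcat <- do.call(cbind, zs[-1])
  sp <- sort_pooling(zcat, sh$k)
  a1 <- sweep(sp$s %*% params$W1, 2, params$b1, "+")
  c1 <- relu(a1)
  # width-2 stride-2 max pooling over the k positions
  t2 <- sh$t2
  odd <- c1[2 * seq_len(t2) - 1, , drop = FALSE]
  evn <- c1[2 * seq_len(t2), , drop = FALSE]
  takeodd <- odd >= evn
  m2 <- ifelse(takeodd, odd, evn)
  # im2col for the width-w2 stride-1 second convolution
  l2 <- sh$l2
  x2 <- do.call(cbind, lapply(0:(sh$w2 - 1), function(s)
    m2[(1 + s):(l2 + s), , drop = FALSE]))
  a2 <- sweep(x2 %*% params$W2, 2, params$b2, "+")
  c2 <- relu(a2)
  h <- as.vector(t(c2))
  ad <- as.vector(h %*% params$Wd) + params$bd
  hd <- relu(ad)
  if (!is.null(drop_mask)) hd <- hd * drop_mask
  logit <- sum(hd * params$Wo) + params$bo
  p <- stats::plogis(logit)
  if (!keep) return(p)
  list(p = p, logit = logit, pr = pr, zs = zs, pzs = pzs, zcat = zcat, sp = sp,
       a1 = a1, c1 = c1, takeodd = takeodd, m2 = m2, x2 = x2, a2 = a2, c2 = c2,
       h = h, ad = ad, hd = hd, drop_mask = drop_mask)
}

# Backward pass: gradients of the binary cross-entropy w.r.t. every
# parameter, for one graph with target y01 in {0, 1}.
dgcnn_backward <- function(fw, params, cfg, y01) {
  sh <- attr(params, "shape")
  gr <- list()
  dlogit <- fw$p - y01
  gr$bo <- dlogit
  gr$Wo <- matrix(fw$hd * dlogit, ncol = 1)
  dhd <- as.vector(params$Wo) * dlogit
  if (!is.null(fw$drop_mask)) dhd <- dhd * fw$drop_mask
  dad <- dhd * (fw$ad > 0)
  gr$bd <- dad
  gr$Wd <- outer(fw$h, dad)
  dh <- as.vector(params$Wd %*% dad)
  dc2 <- matrix(dh, nrow = sh$l2, ncol = sh$f2, byrow = TRUE)
  da2 <- dc2 * (fw$a2 > 0)
  gr$b2 <- colSums(da2)
  gr$W2 <- t(fw$x2) %*% da2
  dx2 <- da2 %*% t(params$W2)
  dm2 <- matrix(0, sh$t2, sh$f1)
  for (s in 0:(sh$w2 - 1)) {
    cols <- (s * sh$f1 + 1):((s + 1) * sh$f1)
    dm2[(1 + s):(sh$l2 + s), ] <- dm2[(1 + s):(sh$l2 + s), ] + dx2[, cols]
  }
  dc1 <- matrix(0, sh$k, sh$f1)
  oddrows <- 2 * seq_len(sh$t2) - 1
  dc1[oddrows, ] <- dm2 * fw$takeodd
  dc1[oddrows + 1, ] <- dm2 * !fw$takeodd
  da1 <- dc1 * (fw$a1 > 0)
  gr$b1 <- colSums(da1)
  gr$W1 <- t(fw$sp$s) %*% da1
  ds <- da1 %*% t(params$W1)
  n <- nrow(fw$zcat)
  dzcat <- matrix(0, n, ncol(fw$zcat))
  real <- seq_len(fw$sp$n_real)
  dzcat[fw$sp$idx[real], ] <- ds[real, , drop = FALSE]
  # split the concatenated gradient and run the conv chain backwards
  ch <- cfg$conv_channels
  ends <- cumsum(ch)
  starts <- ends - ch + 1
  dz <- vector("list", 5)
  for (t in 1:4) dz[[t + 1]] <- dzcat[, starts[t]:ends[t], drop = FALSE]
  for (t in 4:1) {
    zt <- fw$zs[[t + 1]]
    dht <- dz[[t + 1]] * (1 - zt^2)
    gr[[paste0("Wg", t)]] <- t(fw$pzs[[t]]) %*% dht
    down <- prop_backward(fw$pr, dht %*% t(params[[paste0("Wg", t)]]))
    dz[[t]] <- if (is.null(dz[[t]])) down else dz[[t]] + down
  }
  gr
}

# ---- Adam ------------------------------------------------------------------

adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0),
       t = 0)
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1
  for (nm in names(grads)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    mh <- state$m[[nm]] / (1 - beta1^state$t)
    vh <- state$v[[nm]] / (1 - beta2^state$t)
    params[[nm]] <- params[[nm]] - lr * mh / (sqrt(vh) + eps)
  }
  list(params = params, state = state)
}

# ---- fold plan -------------------------------------------------------------

#' Patient-stratified fold plan
#'
#' Assigns every patient to exactly one fold (all cores of a patient share
#' its fold), dealing patients round-robin within each outcome class so
#' per-fold class proportions are within one patient of balance.
#'
#' @param patient_labels tibble with `patient_id` and `label` in `{-1, +1}`.
#' @param n_folds number of folds (default 3).
#' @param seed integer seed.
#' @return a `fold_plan`: tibble (patient_id, label, fold) and `n_folds`.
#' @export
make_fold_plan <- function(patient_labels, n_folds = 3L, seed = 1L) {
  assert_that(all(patient_labels$label %in% c(-1L, 1L)),
              "labels must be -1 or +1")
  set.seed(derive_seed(seed, "folds"))
  rows <- purrr::map(split(patient_labels, patient_labels$label), function(df) {
    df <- df[sample.int(nrow(df)), ]
    df$fold <- rep(seq_len(n_folds), length.out = nrow(df))
    df
  })
  plan <- dplyr::arrange(dplyr::bind_rows(rows), .data$patient_id)
  structure(list(assignment = as_tibble(plan), n_folds = as.integer(n_folds)),
            class = "fold_plan")
}

# ---- training --------------------------------------------------------------

#' Train the deep graph CNN with patient-stratified cross-validation
#'
#' For each fold, trains on the remaining folds and predicts the held-out
#' cores, so every core receives exactly one out-of-fold prediction. Labels
#' are taken from each graph's `label` field (`{-1, +1}`), encoded `{0, 1}`
#' internally for the cross-entropy and mapped back at the decision
#' boundary. Fully seeded: the same configuration and inputs reproduce the
#' same fold models and predictions.
#'
#' @param graphs list of labelled `core_graph` objects.
#' @param plan a `fold_plan` covering every patient in `graphs`.
#' @param config a [dgcnn_config()].
#' @return a `dgcnn_cv`: `models` (one `trained_dgcnn` per fold, each with
#'   parameters, config, `sortpool_k` and per-epoch loss `history`) and
#'   `oof` — tibble (core_id, patient_id, fold, score, pred).
#' @export
train_dgcnn <- function(graphs, plan, config = dgcnn_config()) {
  labels <- vapply(graphs, function(g) g$label, integer(1))
  assert_that(!anyNA(labels), "every graph needs a label in {-1, +1}")
  pids <- vapply(graphs, function(g) g$patient_id, character(1))
  fold_of <- stats::setNames(plan$assignment$fold, plan$assignment$patient_id)
  assert_that(all(pids %in% names(fold_of)), "fold plan misses some patients")
  gfold <- unname(fold_of[pids])
  models <- list()
  oof <- list()
  for (f in seq_len(plan$n_folds)) {
    tr <- which(gfold != f)
    te <- which(gfold == f)
    if (length(unique(labels[tr])) < 2) {
      stop_input(sprintf("training split for fold %d contains one class only", f),
                 "renograph_stratification")
    }
    model <- dgcnn_fit(graphs[tr], labels[tr], config,
                       seed = derive_seed(config$seed, "fold", f))
    models[[f]] <- model
    if (length(te) > 0) {
      sc <- vapply(graphs[te], function(g) dgcnn_forward(g, model$params, config),
                   numeric(1))
      oof[[f]] <- tibble(core_id = vapply(graphs[te], function(g) g$core_id,
                                          character(1)),
                         patient_id = pids[te], fold = f, score = sc,
                         pred = ifelse(sc >= 0.5, 1L, -1L))
    }
  }
  structure(list(models = models, oof = dplyr::bind_rows(oof), config = config,
                 plan = plan),
            class = "dgcnn_cv")
}

# Fit one model on a training set of graphs (single split).
dgcnn_fit <- function(graphs, labels, config, seed = 1L) {
  set.seed(seed)
  n_nodes <- vapply(graphs, function(g) nrow(g$nodes), integer(1))
  k <- config$sortpool_k %||%
    max(10L, as.integer(round(stats::quantile(n_nodes, 0.4, type = 1))))
  m <- ncol(graph_features(graphs[[1]]))
  params <- dgcnn_init(config, m, k)
  state <- adam_init(params)
  y01 <- (labels + 1L) / 2L
  history <- numeric(config$epochs)
  bs <- max(1L, config$batch_size)
  for (ep in seq_len(config$epochs)) {
    ord <- sample.int(length(graphs))
    losses <- numeric(length(ord))
    batches <- split(ord, ceiling(seq_along(ord) / bs))
    for (batch in batches) {
      acc <- NULL
      for (i in batch) {
        dm <- NULL
        if (config$dropout > 0) {
          dm <- (stats::runif(config$dense_units) >= config$dropout) /
            (1 - config$dropout)
        }
        fw <- dgcnn_forward(graphs[[i]], params, config, drop_mask = dm,
                            keep = TRUE)
        p <- clamp(fw$p, 1e-12, 1 - 1e-12)
        losses[match(i, ord)] <- -(y01[i] * log(p) + (1 - y01[i]) * log(1 - p))
        gr <- dgcnn_backward(fw, params, config, y01[i])
        acc <- if (is.null(acc)) gr else
          stats::setNames(lapply(names(gr), function(nm) acc[[nm]] + gr[[nm]]),
                          names(gr))
      }
      acc <- lapply(acc, function(g) g / length(batch))
      upd <- adam_step(params, acc, state, config$learning_rate)
      params <- upd$params
      state <- upd$state
    }
    history[ep] <- mean(losses)
  }
  structure(list(params = params, config = config, sortpool_k = k,
                 input_dim = m, history = history),
            class = "trained_dgcnn")
}

#' Predict the class of one core
#'
#' Sigmoid output >= 0.5 maps to +1, otherwise -1 (the exact boundary lands
#' on +1 by convention).
#'
#' @param model a `trained_dgcnn`.
#' @param graph a `core_graph`.
#' @param score return the raw sigmoid score instead of the class.
#' @return class in `{-1, +1}` (or the score).
#' @export
predict_core <- function(model, graph, score = FALSE) {
  s <- dgcnn_forward(graph, model$params, model$config)
  if (score) return(s)
  if (s >= 0.5) 1L else -1L
}
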