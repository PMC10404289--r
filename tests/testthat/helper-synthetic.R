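# Shared builders for small synthetic objects used across the suite.

# A rectangular full-tissue lattice core_graph with given node features.
lattice_graph <- function(nr, nc, feat = NULL, label = 1L, core_id = "c1",
                          patient_id = "p1") {
  n <- nr * nc
  if (is.null(feat)) feat <- matrix(stats::rnorm(2 * n), n, 2)
  id <- matrix(seq_len(n), nr, nc)
  e <- rbind(
    if (nr > 1) cbind(as.vector(id[-nr, ]), as.vector(id[-1, ])) else NULL,
    if (nc > 1) cbind(as.vector(id[, -nc]), as.vector(id[, -1])) else NULL)
  if (is.null(e)) e <- matrix(integer(0), 0, 2)
  nodes <- tibble::tibble(row = rep(seq_len(nr), nc),
                          col = rep(seq_len(nc), each = nr),
                          cluster = 1L)
  for (j in seq_len(ncol(feat))) nodes[[paste0("x", j)]] <- feat[, j]
  structure(list(core_id = core_id, patient_id = patient_id, nodes = nodes,
                 edges = e, label = as.integer(label)),
            class = "core_graph")
}

# Cohort of separable lattice graphs: the node-feature mean carries the label.
separable_graph_cohort <- function(n_graphs = 42, nr = 5, nc = 6, mu = 0.9,
                                   sd = 0.4, seed = 1) {
  set.seed(seed)
  labs <- rep(c(1L, -1L), length.out = n_graphs)
  graphs <- lapply(seq_len(n_graphs), function(i) {
    n <- nr * nc
    feat <- cbind(stats::rnorm(n, mu * labs[i], sd), stats::rnorm(n, 0, sd))
    lattice_graph(nr, nc, feat, label = labs[i],
                  core_id = sprintf("c%02d", i), patient_id = sprintf("p%02d", i))
  })
  list(graphs = graphs,
       labels = tibble::tibble(patient_id = sprintf("p%02d", seq_len(n_graphs)),
                               label = labs))
}

# Patch features drawn from the built-in extractor over k well-separated
# texture patterns; returns the standardized feature matrix plus ground truth.
pattern_feature_set <- function(k = 4, per = 30, size = 16, seed = 1) {
  pats <- default_patterns(k)
  x <- do.call(rbind, lapply(seq_len(k), function(i) {
    t(vapply(seq_len(per), function(j) {
      builtin_texture_extractor(
        generate_texture_patch(pats[[i]], size, seed = seed * 1000 + i * 100 + j))
    }, numeric(19)))
  }))
  ids <- tibble::tibble(core_id = "c1", patient_id = "p1",
                        row = seq_len(k * per), col = 1L)
  list(fm = standardize_features(feature_matrix(ids, x, "texture")),
       truth = rep(seq_len(k), each = per))
}

# Adjusted Rand index between two labelings (contingency-table formula).
adjusted_rand <- function(a, b) {
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sij <- sum(comb2(tab))
  si <- sum(comb2(rowSums(tab)))
  sj <- sum(comb2(colSums(tab)))
  n2 <- comb2(sum(tab))
  expected <- si * sj / n2
  (sij - expected) / ((si + sj) / 2 - expected)
}

# A tiny rendered cohort for end-to-end tests.
small_cohort <- function(n_patients = 12, seed = 7, k_true = 5,
                         core_shape = c(192, 192), patch_size = 16) {
  generate_cohort(cohort_spec(
    n_patients = n_patients, cores_per_patient = c(2, 3),
    core_shape = core_shape, patch_size = patch_size, k_true = k_true,
    lesion_pattern_ids = 1:2, seed = seed))
}
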