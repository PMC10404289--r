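#' Silhouette-based selection of the number of clusters
#'
#' For each candidate K, fits a seeded k-means on a (seeded) subsample of the
#' features and scores it by the mean silhouette width; returns the argmax
#' (ties broken toward the smallest K). The subsample bounds the quadratic
#' cost of the silhouette computation.
#'
#' @param fm a `feature_matrix`.
#' @param k_range integer vector of candidate K values (each in `[2, n-1]`).
#' @param sample_size maximum number of points scored.
#' @param seed integer seed.
#' @return the selected K (integer).
#' @export
select_k_silhouette <- function(fm, k_range = 5:12, sample_size = 5000L,
                                seed = 1L) {
  n <- nrow(fm$x)
  assert_that(n >= 3, "need at least 3 points to select K",
              "renograph_insufficient")
  k_range <- sort(unique(as.integer(k_range)))
  assert_that(all(k_range >= 2 & k_range <= n - 1),
              "k_range must lie within [2, n-1]")
  if (length(k_range) == 1L) return(k_range)
  set.seed(derive_seed(seed, "silhouette"))
  idx <- if (n > sample_size) sample.int(n, sample_size) else seq_len(n)
  xs <- fm$x[idx, , drop = FALSE]
  dd <- stats::dist(xs)
  score <- vapply(k_range, function(k) {
    cl <- kmeans_lloyd(xs, k, seed = derive_seed(seed, "sil_k", k))
    sil <- cluster::silhouette(cl$cluster, dd)
    mean(sil[, "sil_width"])
  }, numeric(1))
  k_range[which.max(score)]  # which.max takes the first (smallest K) on ties
}

# Seeded k-means++ initialization + Lloyd iterations with restarts.
kmeans_lloyd <- function(x, k, seed = 1L, n_init = 10L, max_iter = 300L) {
  assert_that(k >= 2, "K must be >= 2", "renograph_invalid")
  assert_that(nrow(x) >= k, "K cannot exceed the number of points",
              "renograph_invalid")
  set.seed(seed)
  best <- NULL
  for (r in seq_len(n_init)) {
    centers <- kmeanspp_init(x, k)
    fit <- suppressWarnings(
      stats::kmeans(x, centers = centers, iter.max = max_iter,
                    algorithm = "Lloyd"))
    if (is.null(best) || fit$tot.withinss < best$tot.withinss) best <- fit
  }
  best
}

# k-means++ seeding (D^2 sampling).
kmeanspp_init <- function(x, k) {
  n <- nrow(x)
  centers <- matrix(NA_real_, k, ncol(x))
  centers[1, ] <- x[sample.int(n, 1), ]
  d2 <- rowSums(sweep(x, 2, centers[1, ])^2)
  for (j in 2:k) {
    p <- if (sum(d2) > 0) d2 / sum(d2) else rep(1 / n, n)
    centers[j, ] <- x[sample.int(n, 1, prob = p), ]
    d2 <- pmin(d2, rowSums(sweep(x, 2, centers[j, ])^2))
  }
  # nudge exact duplicates so stats::kmeans accepts the matrix
  while (anyDuplicated(centers)) {
    dup <- which(duplicated(centers))
    centers[dup, ] <- centers[dup, , drop = FALSE] +
      matrix(stats::rnorm(length(dup) * ncol(x), sd = 1e-8), length(dup))
  }
  centers
}

#' Fit the cluster model
#'
#' Seeded k-means (k-means++ initialization, Lloyd updates, 10 restarts)
#' over the patch features, plus the derived MDS ordering, MDS coordinates
#' (the downstream graph node features) and a display palette.
#'
#' @param fm a `feature_matrix` (standardized recommended).
#' @param k number of clusters (>= 2, <= n).
#' @param seed integer seed.
#' @param mds_dim number of MDS coordinates kept as node features.
#' @return a `cluster_model`: `k`, `centroids` (K x d), `mds_order`
#'   (permutation of 1..K, left-to-right histogram order), `mds_coords`
#'   (K x mds_dim), `palette` (K hex colours), `inertia`.
#' @export
fit_kmeans <- function(fm, k, seed = 1L, mds_dim = 2L) {
  fit <- kmeans_lloyd(fm$x, k, seed = derive_seed(seed, "kmeans"))
  mds <- order_clusters_mds(fit$centers, m = mds_dim)
  structure(
    list(k = as.integer(k),
         centroids = unname(fit$centers),
         mds_order = mds$mds_order,
         mds_coords = mds$mds_coords,
         palette = cluster_palette(k),
         inertia = fit$tot.withinss,
         extractor = fm$extractor),
    class = "cluster_model"
  )
}

# Fixed distinct display palette, echoing the conventional pattern colours.
cluster_palette <- function(k) {
  base <- c("#D62728", "#1F77B4", "#2CA02C", "#000000", "#17BECF",
            "#FF7F0E", "#BCBD22", "#000080", "#F2F2F2")
  if (k <= length(base)) return(base[seq_len(k)])
  c(base, grDevices::rainbow(k - length(base)))
}

#' Classical MDS ordering of cluster centroids
#'
#' Torgerson (double-centring) MDS on the K x K Euclidean centroid distance
#' matrix. Clusters are ordered by their first MDS coordinate; because the
#' embedding is reflection-ambiguous the sign is fixed so that, of the two
#' extreme clusters on the first axis, the one with the lower original index
#' sits at the left (negative) end.
#'
#' @param centroids K x d matrix.
#' @param m number of coordinates returned (padded with zeros if the
#'   embedding rank is lower).
#' @return list with `mds_order` (cluster indices left to right) and
#'   `mds_coords` (K x m).
#' @export
order_clusters_mds <- function(centroids, m = 2L) {
  k <- nrow(centroids)
  assert_that(k >= 2, "need at least 2 centroids")
  dd <- stats::dist(centroids)
  if (max(dd) <= 1e-12) {
    stop_input("identical centroids: degenerate distance matrix",
               "renograph_degenerate")
  }
  coords <- stats::cmdscale(dd, k = min(m, k - 1))
  if (ncol(coords) < m) {
    coords <- cbind(coords, matrix(0, k, m - ncol(coords)))
  }
  x1 <- coords[, 1]
  lo <- which.min(x1); hi <- which.max(x1)
  if (hi < lo) coords[, 1] <- -coords[, 1]
  list(mds_order = order(coords[, 1], seq_len(k)),
       mds_coords = unname(coords))
}

#' Nearest-centroid cluster assignment
#'
#' Retains the full point-to-centroid distance matrix; ties go to the lowest
#' cluster index.
#'
#' @param fm a `feature_matrix` with the same dimensionality as the model.
#' @param model a `cluster_model`.
#' @return a `cluster_assignment`: `ids`, `cluster` (integer vector),
#'   `distances` (n x K matrix).
#' @export
assign_clusters <- function(fm, model) {
  if (ncol(fm$x) != ncol(model$centroids)) {
    stop_input(sprintf("feature dimension %d does not match centroid dimension %d",
                       ncol(fm$x), ncol(model$centroids)), "renograph_shape")
  }
  d2 <- outer(rowSums(fm$x^2), rep(1, model$k)) +
    outer(rep(1, nrow(fm$x)), rowSums(model$centroids^2)) -
    2 * fm$x %*% t(model$centroids)
  dmat <- sqrt(pmax(d2, 0))
  structure(
    list(ids = fm$ids,
         cluster = max.col(-dmat, ties.method = "first"),
         distances = dmat),
    class = "cluster_assignment"
  )
}

#' Per-case cluster frequency histogram
#'
#' Bins follow the MDS left-to-right order; proportion mode (default)
#' divides by the case's total patch count so core size does not confound
#' composition (size enters separately through the area-weighted score).
#'
#' @param assignment a `cluster_assignment` covering one or more patients.
#' @param model the `cluster_model`.
#' @param mode `"proportions"` or `"counts"`.
#' @return tibble, one row per patient: patient_id, f1..fK (MDS order),
#'   total_patches.
#' @export
case_histogram <- function(assignment, model, mode = c("proportions", "counts")) {
  mode <- match.arg(mode)
  ids <- assignment$ids
  assert_that(!is.null(ids$patient_id), "assignment ids must carry patient_id")
  pats <- unique(ids$patient_id)
  rows <- purrr::map(pats, function(p) {
    sel <- ids$patient_id == p
    total <- sum(sel)
    if (total == 0) {
      rlang::warn(paste0("patient ", p, " has zero patches; excluded"))
      return(NULL)
    }
    counts <- tabulate(assignment$cluster[sel], nbins = model$k)
    f <- counts[model$mds_order]
    if (mode == "proportions") f <- f / total
    stats::setNames(
      as.data.frame(c(list(patient_id = p), as.list(f), list(total_patches = total))),
      c("patient_id", paste0("f", seq_len(model$k)), "total_patches")
    )
  })
  as_tibble(dplyr::bind_rows(rows))
}

#' Quartic trend coefficients of a case histogram
#'
#' Least-squares fit of `f(x) = c1 x^4 + c2 x^3 + c3 x^2 + c4 x + c5` over
#' the ordinal bin positions `x = 1..K` (MDS order). The five coefficients
#' summarize the overall shape of the frequency profile.
#'
#' @param freqs numeric vector of K >= 5 bin frequencies, or a one-row
#'   histogram tibble from [case_histogram()].
#' @return named numeric vector c1..c5 (degree 4 down to the constant).
#' @export
fit_poly4 <- function(freqs) {
  if (is.data.frame(freqs)) {
    freqs <- as.numeric(freqs[1, grep("^f\\d+$", names(freqs))])
  }
  k <- length(freqs)
  assert_that(k >= 5, "quartic fit needs at least 5 bins",
              "renograph_underdetermined")
  x <- seq_len(k)
  fit <- stats::lm.fit(cbind(x^4, x^3, x^2, x, 1), freqs)
  stats::setNames(fit$coefficients, paste0("c", 1:5))
}

#' Quartic trend coefficients for every case
#' @param hists histogram tibble from [case_histogram()].
#' @return tibble: patient_id, c1..c5.
#' @export
poly4_table <- function(hists) {
  fcols <- grep("^f\\d+$", names(hists), value = TRUE)
  rows <- purrr::map(seq_len(nrow(hists)), function(i) {
    cc <- fit_poly4(as.numeric(hists[i, fcols]))
    as.data.frame(c(list(patient_id = hists$patient_id[i]), as.list(cc)))
  })
  as_tibble(dplyr::bind_rows(rows))
}

#' Serialize a cluster model to JSON
#' @param model a `cluster_model`.
#' @param path output path.
#' @export
write_cluster_model <- function(model, path) {
  jsonlite::write_json(
    list(k = model$k, centroids = model$centroids,
         mds_order = model$mds_order, mds_coords = model$mds_coords,
         palette = model$palette, inertia = model$inertia,
         extractor = model$extractor),
    path, digits = NA)
  invisible(path)
}

#' Read a cluster model from JSON
#' @param path path written by [write_cluster_model()].
#' @export
read_cluster_model <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(
    list(k = as.integer(x$k), centroids = as.matrix(x$centroids),
         mds_order = as.integer(x$mds_order), mds_coords = as.matrix(x$mds_coords),
         palette = x$palette, inertia = x$inertia, extractor = x$extractor),
    class = "cluster_model")
}
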