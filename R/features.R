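# Extractor registry. Downstream modules consume only the feature matrix,
# never the extractor, so extractors are swappable without interface changes.
.extractors <- new.env(parent = emptyenv())

#' Register a patch feature extractor
#'
#' @param name extractor name.
#' @param fn function(patch_array) -> numeric vector of fixed length.
#' @param d output dimension.
#' @export
register_extractor <- function(name, fn, d) {
  assert_that(is.function(fn) && d >= 1, "fn must be a function, d >= 1")
  assign(name, list(fn = fn, d = as.integer(d)), envir = .extractors)
  invisible(name)
}

get_extractor <- function(name) {
  if (!exists(name, envir = .extractors, inherits = FALSE)) {
    stop_input(paste0("no extractor registered under '", name, "'"),
               "renograph_config")
  }
  get(name, envir = .extractors, inherits = FALSE)
}

#' Built-in deterministic texture extractor
#'
#' A 19-dimensional hand-crafted descriptor used as the desk-scale stand-in
#' for pretrained-CNN activations. Components, in order:
#' \enumerate{
#'   \item per-channel RGB means (3),
#'   \item per-channel RGB standard deviations (3),
#'   \item Lab channel means (3),
#'   \item 8-bin gradient-orientation histogram, orientations mod pi,
#'     magnitude-weighted and divided by pixel count (8),
#'   \item 4-level grey co-occurrence contrast and energy (2).
#' }
#'
#' @param patch H x W x 3 numeric array on the 0..255 scale.
#' @return numeric vector of length 19.
#' @export
builtin_texture_extractor <- function(patch) {
  px <- pixel_matrix(patch)
  mu <- colMeans(px)
  sg <- apply(px, 2, stats::sd)
  lab_mu <- colMeans(rgb_to_lab(px))
  g <- (0.299 * patch[, , 1] + 0.587 * patch[, , 2] + 0.114 * patch[, , 3]) / 255
  h <- nrow(g); w <- ncol(g)
  # central differences on the interior
  gy <- (g[3:h, 2:(w - 1)] - g[1:(h - 2), 2:(w - 1)]) / 2
  gx <- (g[2:(h - 1), 3:w] - g[2:(h - 1), 1:(w - 2)]) / 2
  mag <- sqrt(gx^2 + gy^2)
  ori <- atan2(gy, gx) %% pi
  bin <- pmin(floor(ori / (pi / 8)) + 1L, 8L)
  ghist <- vapply(1:8, function(b) sum(mag[bin == b]), numeric(1)) / (h * w)
  # 4-level GLCM, horizontal offset 1, symmetric
  q <- pmin(floor(g * 4) + 1L, 4L)
  a <- q[, 1:(w - 1)]; b <- q[, 2:w]
  counts <- tabulate((a - 1L) * 4L + b, nbins = 16L)
  glcm <- matrix(counts, 4, 4, byrow = TRUE)
  glcm <- glcm + t(glcm)
  p <- glcm / sum(glcm)
  ij <- outer(1:4, 1:4, "-")
  contrast <- sum(p * ij^2)
  energy <- sum(p^2)
  unname(c(mu, sg, lab_mu, ghist, contrast, energy))
}

.builtin_d <- 19L

#' Feature extraction over a patch grid
#'
#' One feature vector per retained patch, in grid entry (row-major) order.
#' Deterministic for the built-in extractor.
#'
#' @param grid a `patch_grid` from [tile_core()].
#' @param extractor registered extractor name.
#' @return a `feature_matrix` object: `ids` tibble (core_id, row, col),
#'   `x` (n x d matrix), `extractor`, `d`.
#' @export
extract_features <- function(grid, extractor = "texture") {
  assert_that(nrow(grid$entries) > 0, "empty patch grid", "renograph_empty")
  ex <- get_extractor(extractor)
  x <- matrix(NA_real_, nrow(grid$entries), ex$d)
  for (i in seq_len(nrow(grid$entries))) {
    v <- ex$fn(grid_patch(grid, i))
    if (length(v) != ex$d) {
      stop_input(sprintf("extractor '%s' returned length %d, expected %d",
                         extractor, length(v), ex$d), "renograph_shape")
    }
    x[i, ] <- v
  }
  feature_matrix(
    ids = tibble(core_id = grid$core$core_id,
                 patient_id = grid$core$patient_id,
                 row = grid$entries$row, col = grid$entries$col),
    x = x, extractor = extractor)
}

#' Construct a feature matrix object
#' @param ids tibble with core_id, patient_id, row, col per patch.
#' @param x n x d numeric matrix, no missing values.
#' @param extractor extractor name that produced `x`.
#' @export
feature_matrix <- function(ids, x, extractor) {
  assert_that(nrow(ids) == nrow(x), "ids and x row counts differ")
  assert_that(!anyNA(x) && all(is.finite(x)), "feature matrix has non-finite values")
  structure(list(ids = ids, x = x, extractor = extractor, d = ncol(x)),
            class = "feature_matrix")
}

#' Combine per-core feature matrices
#' @param fms list of `feature_matrix` objects from the same extractor.
#' @export
bind_features <- function(fms) {
  ex <- unique(vapply(fms, function(f) f$extractor, character(1)))
  assert_that(length(ex) == 1, "all feature matrices must share one extractor")
  feature_matrix(dplyr::bind_rows(purrr::map(fms, "ids")),
                 do.call(rbind, purrr::map(fms, "x")), ex)
}

#' Z-score feature standardization
#'
#' Per-dimension centring and scaling across the cohort, applied before
#' clustering so no single raw scale dominates the distance metric.
#' Zero-variance dimensions are centred only.
#'
#' @param fm a `feature_matrix`.
#' @param center,scale optional pre-computed statistics (for applying a
#'   training standardization to new data).
#' @return standardized `feature_matrix` with `center`/`scale` attached.
#' @export
standardize_features <- function(fm, center = NULL, scale = NULL) {
  center <- center %||% colMeans(fm$x)
  scale <- scale %||% apply(fm$x, 2, stats::sd)
  scale[!is.finite(scale) | scale <= 1e-12] <- 1
  out <- feature_matrix(fm$ids, sweep(sweep(fm$x, 2, center), 2, scale, "/"),
                        fm$extractor)
  out$center <- center
  out$scale <- scale
  out
}

#' Write a feature matrix as CSV (+ JSON sidecar naming the extractor)
#' @param fm a `feature_matrix`.
#' @param path CSV output path.
#' @export
write_features <- function(fm, path) {
  df <- cbind(as.data.frame(fm$ids),
              stats::setNames(as.data.frame(fm$x), paste0("v", seq_len(fm$d))))
  utils::write.csv(df, path, row.names = FALSE)
  jsonlite::write_json(list(extractor = fm$extractor, d = fm$d),
                       paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}
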