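#' Biopsy core image container
#'
#' @param patient_id,core_id identifiers.
#' @param pixels H x W x 3 numeric array on the 0..255 scale (may be NULL for
#'   ground-truth-only synthetic cores).
#' @param tissue_mask H x W logical matrix, or NULL to defer to
#'   [tissue_mask()].
#' @param pixel_size_um optional physical pixel size.
#' @return a `core_image` object.
#' @export
core_image <- function(patient_id, core_id, pixels, tissue_mask = NULL,
                       pixel_size_um = NULL) {
  if (!is.null(pixels) && !is.null(tissue_mask)) {
    assert_that(all(dim(tissue_mask) == dim(pixels)[1:2]),
                "tissue_mask dimensions must match pixels")
  }
  structure(
    list(patient_id = patient_id, core_id = core_id, pixels = pixels,
         tissue_mask = tissue_mask, pixel_size_um = pixel_size_um),
    class = "core_image"
  )
}

#' Read a core image from PNG or TIFF
#'
#' @param path image file path.
#' @param patient_id,core_id identifiers; default derived from the filename.
#' @return a [core_image()] (mask unset; see [tissue_mask()]).
#' @export
read_core_image <- function(path, patient_id = NULL, core_id = NULL) {
  ext <- tolower(tools::file_ext(path))
  raw <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    stop_input(paste0("unsupported image format: ", ext), "renograph_io"))
  if (length(dim(raw)) == 2L) raw <- array(rep(raw, 3), dim = c(dim(raw), 3))
  if (dim(raw)[3] > 3L) raw <- raw[, , 1:3, drop = FALSE]
  cid <- core_id %||% tools::file_path_sans_ext(basename(path))
  core_image(patient_id %||% cid, cid, pixels = raw * 255)
}

#' Pooled Lab reference statistics
#'
#' Per-channel mean and standard deviation in CIE Lab, pooled over all pixels
#' (tissue pixels only by default) of a collection of cores. Used as the
#' global reference for Reinhard stain normalization.
#'
#' @param images list of [core_image()] objects.
#' @param masked pool tissue pixels only (requires masks on the cores).
#' @return a `lab_reference_stats` object: `mean` and `sd`, each length 3
#'   (L, a, b).
#' @export
compute_lab_stats <- function(images, masked = TRUE) {
  assert_that(length(images) > 0, "empty image collection", "renograph_empty")
  s1 <- s2 <- c(0, 0, 0)
  n <- 0
  for (img in images) {
    px <- pixel_matrix(img$pixels)
    if (masked) {
      assert_that(!is.null(img$tissue_mask),
                  "masked = TRUE requires tissue masks on every core")
      px <- px[as.vector(img$tissue_mask), , drop = FALSE]
    }
    lab <- rgb_to_lab(px)
    s1 <- s1 + colSums(lab)
    s2 <- s2 + colSums(lab^2)
    n <- n + nrow(lab)
  }
  assert_that(n > 1, "not enough pixels to pool", "renograph_empty")
  mean <- s1 / n
  sd <- sqrt(pmax(0, s2 / n - mean^2))
  if (any(sd <= 1e-8)) {
    stop_input("degenerate Lab statistics: zero variance on a channel",
               "renograph_degenerate")
  }
  structure(list(mean = mean, sd = sd, n_pixels = n),
            class = "lab_reference_stats")
}

#' Reinhard stain colour normalization
#'
#' Linearly maps each Lab channel of `image` to the reference mean and
#' standard deviation: `out = (in - mean_in) / sd_in * sd_ref + mean_ref`,
#' then converts back to sRGB with gamut clipping. A channel with zero input
#' spread is mean-shifted only (with a warning) rather than rescaled.
#'
#' @param image H x W x 3 numeric array (0..255) or a [core_image()].
#' @param ref a `lab_reference_stats` object.
#' @param mask optional logical matrix: compute the input statistics over
#'   these pixels only (the transform is still applied to every pixel).
#' @return object of the same type as `image`, normalized.
#' @export
reinhard_normalize <- function(image, ref, mask = NULL) {
  is_core <- inherits(image, "core_image")
  px_img <- if (is_core) image$pixels else image
  assert_that(length(px_img) > 0, "empty image", "renograph_empty")
  assert_that(inherits(ref, "lab_reference_stats"), "ref must be lab_reference_stats")
  h <- dim(px_img)[1]; w <- dim(px_img)[2]
  lab <- rgb_to_lab(pixel_matrix(px_img))
  stat_rows <- if (is.null(mask)) lab else lab[as.vector(mask), , drop = FALSE]
  mu <- colMeans(stat_rows)
  sg <- apply(stat_rows, 2, stats::sd)
  out <- lab
  for (ch in 1:3) {
    if (is.na(sg[ch]) || sg[ch] <= 1e-8) {
      rlang::warn(paste0("Lab channel ", ch,
                         " has zero spread; applying mean shift only"))
      out[, ch] <- lab[, ch] - mu[ch] + ref$mean[ch]
    } else {
      out[, ch] <- (lab[, ch] - mu[ch]) / sg[ch] * ref$sd[ch] + ref$mean[ch]
    }
  }
  res <- matrix_to_image(lab_to_rgb(out), h, w)
  if (is_core) { image$pixels <- res; image } else res
}

#' Heuristic tissue mask
#'
#' A pixel is tissue when it is not background white: luminance below
#' `lum_threshold` or saturation above `sat_threshold`. Connected tissue
#' blobs smaller than `min_object_px` pixels are removed.
#'
#' @param image H x W x 3 numeric array (0..255) or a [core_image()].
#' @param lum_threshold luminance cutoff in `[0, 1]`.
#' @param sat_threshold saturation cutoff in `[0, 1]`.
#' @param min_object_px minimum connected-object size kept.
#' @return logical H x W matrix (or the `core_image` with its mask set).
#' @export
tissue_mask <- function(image, lum_threshold = 0.92, sat_threshold = 0.08,
                        min_object_px = 64L) {
  is_core <- inherits(image, "core_image")
  px_img <- if (is_core) image$pixels else image
  h <- dim(px_img)[1]; w <- dim(px_img)[2]
  px <- pixel_matrix(px_img)
  m <- matrix(luminance01(px) < lum_threshold | saturation01(px) > sat_threshold,
              h, w)
  if (any(m) && min_object_px > 1) {
    lab <- EBImage::bwlabel(m)
    sizes <- tabulate(lab[lab > 0])
    keep <- which(sizes >= min_object_px)
    m <- matrix(lab %in% keep, h, w)
  }
  if (is_core) { image$tissue_mask <- m; image } else m
}

#' Tile a core into a non-overlapping patch grid
#'
#' Grid anchored at the image origin; trailing partial tiles are dropped. A
#' patch is retained iff its tissue fraction is at least `min_tissue_frac`.
#' The (row, col) lattice indices define spatial adjacency downstream.
#'
#' @param core a [core_image()] with pixels and tissue mask.
#' @param patch_size patch side length in pixels (>= 8).
#' @param min_tissue_frac minimum tissue fraction per retained patch.
#' @return a `patch_grid` object: the core, `patch_size`, `n_rows`/`n_cols`,
#'   and `entries` — a tibble (row, col, y0, x0, tissue_fraction) in
#'   row-major order.
#' @export
tile_core <- function(core, patch_size = 256L, min_tissue_frac = 0.5) {
  assert_that(patch_size >= 8, "patch_size must be >= 8")
  assert_that(min_tissue_frac >= 0 && min_tissue_frac <= 1,
              "min_tissue_frac must be in [0, 1]")
  mask <- core$tissue_mask
  assert_that(!is.null(mask), "core has no tissue mask; run tissue_mask() first")
  h <- nrow(mask); w <- ncol(mask)
  nr <- h %/% patch_size; nc <- w %/% patch_size
  if (nr == 0 || nc == 0) {
    rlang::warn("core smaller than one patch; empty grid")
    entries <- tibble(row = integer(), col = integer(), y0 = integer(),
                      x0 = integer(), tissue_fraction = numeric())
  } else {
    mm <- mask[seq_len(nr * patch_size), seq_len(nc * patch_size), drop = FALSE]
    # block sums via two rowsum passes
    byrow <- rowsum(mm + 0, rep(seq_len(nr), each = patch_size))
    frac <- t(rowsum(t(byrow), rep(seq_len(nc), each = patch_size))) / patch_size^2
    entries <- tibble(
      row = rep(seq_len(nr), times = nc),
      col = rep(seq_len(nc), each = nr),
      tissue_fraction = as.vector(frac)
    ) |>
      dplyr::mutate(y0 = (.data$row - 1L) * patch_size,
                    x0 = (.data$col - 1L) * patch_size) |>
      dplyr::filter(.data$tissue_fraction >= min_tissue_frac) |>
      dplyr::arrange(.data$row, .data$col) |>
      dplyr::select("row", "col", "y0", "x0", "tissue_fraction")
  }
  structure(
    list(core = core, patch_size = as.integer(patch_size),
         n_rows = nr, n_cols = nc, entries = entries),
    class = "patch_grid"
  )
}

#' Extract the pixel block of one grid patch
#'
#' @param grid a `patch_grid`.
#' @param i entry index (row of `grid$entries`).
#' @return patch_size x patch_size x 3 array.
#' @export
grid_patch <- function(grid, i) {
  e <- grid$entries[i, ]
  ps <- grid$patch_size
  grid$core$pixels[(e$y0 + 1):(e$y0 + ps), (e$x0 + 1):(e$x0 + ps), , drop = FALSE]
}

#' @export
print.patch_grid <- function(x, ...) {
  cat("<patch_grid>", x$core$core_id, ":", nrow(x$entries), "patches of",
      x$patch_size, "px on a", x$n_rows, "x", x$n_cols, "lattice\n")
  invisible(x)
}

#' Serialize Lab reference statistics to JSON
#' @param stats a `lab_reference_stats` object.
#' @param path output path.
#' @export
write_lab_stats <- function(stats, path) {
  jsonlite::write_json(list(mean = stats$mean, sd = stats$sd,
                            n_pixels = stats$n_pixels),
                       path, digits = NA, auto_unbox = FALSE)
  invisible(path)
}

#' Read Lab reference statistics from JSON
#' @param path JSON path written by [write_lab_stats()].
#' @export
read_lab_stats <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(mean = x$mean, sd = x$sd, n_pixels = x$n_pixels),
            class = "lab_reference_stats")
}
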