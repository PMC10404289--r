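#' Texture pattern definition
#'
#' A synthetic local tissue texture: a base colour modulated by one of four
#' procedural texture kinds plus Gaussian pixel noise. Patterns stand in for
#' the visually distinct structures (glomeruli, tubulointerstitium, fibrosis,
#' white space, ...) that clustering discovers in real trichrome-stained
#' biopsies.
#'
#' @param pattern_id integer id, 1..K.
#' @param base_color length-3 RGB vector on the 0..255 scale.
#' @param texture_kind one of `"stripes"`, `"blobs"`, `"speckle"`, `"smooth"`.
#' @param noise_sd nonnegative Gaussian pixel-noise standard deviation
#'   (8-bit units).
#' @return a `texture_pattern` object.
#' @export
texture_pattern <- function(pattern_id, base_color, texture_kind, noise_sd = 6) {
  assert_that(texture_kind %in% c("stripes", "blobs", "speckle", "smooth"),
              paste0("unknown texture_kind '", texture_kind, "'"),
              "renograph_invalid_spec")
  assert_that(noise_sd >= 0, "noise_sd must be >= 0")
  assert_that(length(base_color) == 3 && all(base_color >= 0 & base_color <= 255),
              "base_color must be an RGB triple in 0..255")
  structure(
    list(pattern_id = as.integer(pattern_id),
         base_color = as.numeric(base_color),
         texture_kind = texture_kind,
         noise_sd = noise_sd),
    class = "texture_pattern"
  )
}

#' Default texture pattern set
#'
#' K visually well-separated patterns with distinct base colours (loosely
#' echoing a trichrome palette: collagen blues/greens, cytoplasm reds,
#' nuclei darks, luminal near-whites) and alternating texture kinds.
#'
#' @param k number of patterns (2..9 supplied built-in; more cycle hues).
#' @param noise_sd pixel noise for every pattern.
#' @return list of [texture_pattern()] objects.
#' @export
default_patterns <- function(k = 9, noise_sd = 6) {
  assert_that(k >= 2, "need at least 2 patterns")
  base <- list(
    c(190, 60, 60),    # red
    c(70, 90, 190),    # blue
    c(80, 160, 90),    # green
    c(70, 70, 70),     # dark grey
    c(80, 180, 185),   # cyan
    c(210, 140, 60),   # orange
    c(200, 195, 80),   # yellow
    c(45, 50, 120),    # navy
    c(225, 222, 230)   # near-white luminal space
  )
  kinds <- c("stripes", "blobs", "speckle", "smooth")
  lapply(seq_len(k), function(i) {
    col <- base[[(i - 1L) %% length(base) + 1L]]
    if (i > length(base)) col <- clamp(col + 40 * ((i - 1) %/% length(base)), 0, 240)
    kind <- if (identical(col, base[[9]])) "smooth" else kinds[(i - 1L) %% 4L + 1L]
    texture_pattern(i, col, kind, noise_sd)
  })
}

#' Synthetic cohort specification
#'
#' Describes a synthetic biopsy cohort: patient count, cores per patient,
#' core geometry, the true number of texture patterns, which patterns are
#' "lesion" patterns, and the strength of the (logistic) link between lesion
#' burden / lesion contiguity and the dichotomized outcome.
#'
#' The outcome model is `P(label = +1) = plogis(intercept +
#' effect_size * (lesion fraction - 0.5) + spatial_effect * (contiguity - 0.5))`,
#' with covariates centred so that `intercept = 0` yields balanced cohorts.
#'
#' @param n_patients number of patients (>= 2).
#' @param cores_per_patient integer range `c(min, max)` of cores per patient.
#' @param core_shape `c(height, width)` in pixels.
#' @param patch_size ground-truth grid cell size in pixels; the same grid the
#'   pipeline tiles on.
#' @param k_true number of distinct texture patterns (>= 2).
#' @param lesion_pattern_ids subset of `1..k_true` considered lesional.
#' @param effect_size log-odds of outcome per unit (centred) lesion fraction.
#' @param spatial_effect log-odds per unit (centred) lesion contiguity.
#' @param intercept baseline log-odds.
#' @param noise_sd texture pixel noise.
#' @param seed integer seed; the whole cohort is a pure function of the spec.
#' @return a `cohort_spec` object.
#' @export
cohort_spec <- function(n_patients,
                        cores_per_patient = c(2L, 4L),
                        core_shape = c(512L, 512L),
                        patch_size = 32L,
                        k_true = 9L,
                        lesion_pattern_ids = NULL,
                        effect_size = 6,
                        spatial_effect = 4,
                        intercept = 0,
                        noise_sd = 6,
                        seed = 1L) {
  assert_that(n_patients >= 2, "n_patients must be >= 2")
  assert_that(k_true >= 2, "k_true must be >= 2")
  lesion_pattern_ids <- lesion_pattern_ids %||% seq_len(max(1L, floor(k_true / 3)))
  assert_that(all(lesion_pattern_ids %in% seq_len(k_true)) &&
                length(lesion_pattern_ids) < k_true,
              "lesion_pattern_ids must be a proper subset of 1..k_true")
  structure(
    list(n_patients = as.integer(n_patients),
         cores_per_patient = as.integer(cores_per_patient),
         core_shape = as.integer(core_shape),
         patch_size = as.integer(patch_size),
         k_true = as.integer(k_true),
         lesion_pattern_ids = as.integer(lesion_pattern_ids),
         effect_size = effect_size,
         spatial_effect = spatial_effect,
         intercept = intercept,
         noise_sd = noise_sd,
         seed = as.integer(seed)),
    class = "cohort_spec"
  )
}

#' Generate one texture patch
#'
#' Deterministic: the same (pattern, size, seed) always yields bit-identical
#' pixels.
#'
#' @param pattern a [texture_pattern()].
#' @param size patch side length in pixels (>= 8).
#' @param seed integer seed.
#' @return `size x size x 3` numeric array on the 0..255 scale.
#' @export
generate_texture_patch <- function(pattern, size, seed = 0L) {
  assert_that(inherits(pattern, "texture_pattern"), "pattern must be a texture_pattern",
              "renograph_invalid_spec")
  assert_that(size >= 8, "size must be >= 8")
  set.seed(derive_seed(seed, "patch", pattern$pattern_id))
  base <- pattern$base_color
  # multiplicative luminance modulation, mean-preserving by construction
  modul <- switch(pattern$texture_kind,
    smooth = matrix(1, size, size),
    stripes = {
      period <- max(2L, size %/% 8L)
      band <- ((seq_len(size) - 1L) %/% period) %% 2L
      matrix(rep(1 + 0.18 * (2 * band - 1), each = size), size, size)
    },
    blobs = {
      g <- max(4L, size %/% 8L)
      field <- matrix(stats::rnorm(g * g), g, g)
      up <- field[rep(seq_len(g), each = ceiling(size / g))[seq_len(size)],
                  rep(seq_len(g), each = ceiling(size / g))[seq_len(size)]]
      lo <- up <= stats::median(up)
      matrix(ifelse(lo, 1 - 0.14, 1 + 0.14), size, size)
    },
    speckle = {
      matrix(1 + 0.14 * sign(stats::runif(size * size) - 0.5), size, size)
    },
    stop_input(paste0("unknown texture_kind '", pattern$texture_kind, "'"),
               "renograph_invalid_spec")
  )
  img <- array(0, dim = c(size, size, 3))
  for (ch in 1:3) {
    layer <- base[ch] * modul
    if (pattern$noise_sd > 0) {
      layer <- layer + matrix(stats::rnorm(size * size, sd = pattern$noise_sd), size, size)
    }
    img[, , ch] <- clamp(layer, 0, 255)
  }
  img
}

# ---- lattice helpers -------------------------------------------------------

# 4-neighbour offsets on an (r, c) lattice.
.rook <- cbind(c(-1L, 1L, 0L, 0L), c(0L, 0L, -1L, 1L))

# Connected-component labels of a logical lattice (4-connectivity), BFS.
lattice_components <- function(mask) {
  lab <- matrix(0L, nrow(mask), ncol(mask))
  cur <- 0L
  for (r in seq_len(nrow(mask))) for (c in seq_len(ncol(mask))) {
    if (mask[r, c] && lab[r, c] == 0L) {
      cur <- cur + 1L
      queue <- matrix(c(r, c), ncol = 2)
      lab[r, c] <- cur
      while (nrow(queue) > 0) {
        p <- queue[1, , drop = TRUE]
        queue <- queue[-1, , drop = FALSE]
        for (k in 1:4) {
          rr <- p[1] + .rook[k, 1]; cc <- p[2] + .rook[k, 2]
          if (rr >= 1 && rr <= nrow(mask) && cc >= 1 && cc <= ncol(mask) &&
              mask[rr, cc] && lab[rr, cc] == 0L) {
            lab[rr, cc] <- cur
            queue <- rbind(queue, c(rr, cc))
          }
        }
      }
    }
  }
  lab
}

# Smooth random field on an nr x nc lattice (box-blurred white noise).
smooth_field <- function(nr, nc, passes = 3L) {
  f <- matrix(stats::rnorm(nr * nc), nr, nc)
  for (i in seq_len(passes)) {
    g <- f
    g[-1, ] <- g[-1, ] + f[-nr, ]
    g[-nr, ] <- g[-nr, ] + f[-1, ]
    g[, -1] <- g[, -1] + f[, -nc]
    g[, -nc] <- g[, -nc] + f[, -1]
    f <- g / 5
  }
  f
}

# Blob-shaped tissue cell set on the patch lattice: largest connected
# component of a thresholded smooth field, covering roughly target_frac.
tissue_lattice <- function(nr, nc, target_frac) {
  f <- smooth_field(nr, nc)
  mask <- f <= stats::quantile(f, target_frac)
  lab <- lattice_components(mask)
  if (max(lab) == 0L) {
    mask[] <- FALSE
    mask[max(1, nr %/% 2), max(1, nc %/% 2)] <- TRUE
    return(mask)
  }
  sizes <- tabulate(lab[lab > 0])
  lab == which.max(sizes)
}

# Grow a contiguous lesion set of exactly m cells inside `tissue` (one CC),
# starting from n_seeds random seeds.
grow_lesion <- function(tissue, m, n_seeds) {
  cells <- which(tissue, arr.ind = TRUE)
  n <- nrow(cells)
  if (m <= 0) return(matrix(FALSE, nrow(tissue), ncol(tissue)))
  if (m >= n) return(tissue)
  lesion <- matrix(FALSE, nrow(tissue), ncol(tissue))
  seeds <- cells[sample.int(n, min(n_seeds, n)), , drop = FALSE]
  frontier <- seeds
  taken <- 0L
  while (taken < m) {
    if (nrow(frontier) == 0) {
      # all current blobs saturated; restart from any untaken tissue cell
      remaining <- which(tissue & !lesion, arr.ind = TRUE)
      frontier <- remaining[sample.int(nrow(remaining), 1L), , drop = FALSE]
    }
    i <- sample.int(nrow(frontier), 1L)
    p <- frontier[i, , drop = TRUE]
    frontier <- frontier[-i, , drop = FALSE]
    if (lesion[p[1], p[2]]) next
    lesion[p[1], p[2]] <- TRUE
    taken <- taken + 1L
    for (k in 1:4) {
      rr <- p[1] + .rook[k, 1]; cc <- p[2] + .rook[k, 2]
      if (rr >= 1 && rr <= nrow(tissue) && cc >= 1 && cc <= ncol(tissue) &&
          tissue[rr, cc] && !lesion[rr, cc]) {
        frontier <- rbind(frontier, c(rr, cc))
      }
    }
  }
  lesion
}

# Assign each TRUE cell the pattern id of its nearest seed (lattice Euclidean),
# seeds drawn one per pattern id. Produces contiguous Voronoi-style regions.
voronoi_patterns <- function(cellmask, pattern_ids) {
  cells <- which(cellmask, arr.ind = TRUE)
  out <- matrix(NA_integer_, nrow(cellmask), ncol(cellmask))
  if (nrow(cells) == 0) return(out)
  k <- min(length(pattern_ids), nrow(cells))
  seeds <- cells[sample.int(nrow(cells), k), , drop = FALSE]
  ids <- pattern_ids[seq_len(k)]
  d2 <- outer(cells[, 1], seeds[, 1], "-")^2 + outer(cells[, 2], seeds[, 2], "-")^2
  nearest <- max.col(-d2, ties.method = "first")
  out[cells] <- ids[nearest]
  out
}

#' Generate one synthetic biopsy core
#'
#' A blob-shaped tissue region (aligned to the ground-truth patch grid) on a
#' white background; tissue is partitioned into spatially contiguous regions,
#' each filled with one texture pattern. The number of lesion-pattern patches
#' is exactly `round(lesion_fraction * n_tissue_patches)`.
#'
#' @param spec a [cohort_spec()].
#' @param lesion_fraction target fraction of tissue patches carrying lesion
#'   patterns, in `[0, 1]`.
#' @param seed integer seed.
#' @param render if `FALSE`, skip pixel rendering (labels and mask only);
#'   used for label-distribution studies at scale.
#' @param n_lesion_seeds number of lesion growth seeds (controls contiguity);
#'   default drawn 1..4.
#' @return list with `pixels` (H x W x 3, 0..255, or NULL), `tissue_mask`
#'   (H x W logical), `labels` (lattice matrix of pattern ids, NA off-tissue),
#'   `lesion_fraction` (realized), `contiguity` (see [lesion_contiguity()]).
#' @export
generate_synthetic_core <- function(spec, lesion_fraction, seed = 0L,
                                    render = TRUE, n_lesion_seeds = NULL) {
  assert_that(lesion_fraction >= 0 && lesion_fraction <= 1,
              "lesion_fraction must be in [0, 1]", "renograph_range")
  ps <- spec$patch_size
  nr <- spec$core_shape[1] %/% ps
  nc <- spec$core_shape[2] %/% ps
  set.seed(derive_seed(seed, "core"))
  tissue <- tissue_lattice(nr, nc, stats::runif(1, 0.35, 0.65))
  n_tissue <- sum(tissue)
  m <- round(lesion_fraction * n_tissue)
  n_seeds <- n_lesion_seeds %||% sample.int(4L, 1L)
  lesion <- grow_lesion(tissue, m, n_seeds)
  labels <- matrix(NA_integer_, nr, nc)
  les_ids <- spec$lesion_pattern_ids
  nonles_ids <- setdiff(seq_len(spec$k_true), les_ids)
  labels[lesion] <- voronoi_patterns(lesion, sample(les_ids))[lesion]
  normal <- tissue & !lesion
  labels[normal] <- voronoi_patterns(normal, sample(nonles_ids))[normal]

  h <- nr * ps; w <- nc * ps
  mask <- matrix(FALSE, h, w)
  pixels <- NULL
  patterns <- default_patterns(spec$k_true, spec$noise_sd)
  # rendering reseeds per patch; preserve the structural RNG stream so the
  # same core (and everything drawn after it) is identical with or without
  # pixel rendering
  rng_state <- get(".Random.seed", envir = globalenv())
  if (render) pixels <- array(255, dim = c(h, w, 3))
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    if (!tissue[r, c]) next
    rows <- ((r - 1) * ps + 1):(r * ps)
    cols <- ((c - 1) * ps + 1):(c * ps)
    mask[rows, cols] <- TRUE
    if (render) {
      pixels[rows, cols, ] <- generate_texture_patch(
        patterns[[labels[r, c]]], ps, seed = derive_seed(seed, "cell", r, c))
    }
  }
  assign(".Random.seed", rng_state, envir = globalenv())
  list(pixels = pixels,
       tissue_mask = mask,
       labels = labels,
       lesion_fraction = if (n_tissue > 0) m / n_tissue else 0,
       contiguity = lesion_contiguity(labels, les_ids))
}

#' Lesion contiguity index of a labelled lattice
#'
#' The fraction of lesion patches all of whose within-tissue 4-neighbours are
#' also lesion patches (lesion patches with no tissue neighbours count as
#' contiguous). Returns 0 when there are no lesion patches.
#'
#' @param labels lattice matrix of pattern ids (NA off-tissue).
#' @param lesion_ids lesion pattern ids.
#' @return real in `[0, 1]`.
#' @export
lesion_contiguity <- function(labels, lesion_ids) {
  les <- !is.na(labels) & labels %in% lesion_ids
  cells <- which(les, arr.ind = TRUE)
  if (nrow(cells) == 0) return(0)
  interior <- vapply(seq_len(nrow(cells)), function(i) {
    r <- cells[i, 1]; c <- cells[i, 2]
    ok <- TRUE
    for (k in 1:4) {
      rr <- r + .rook[k, 1]; cc <- c + .rook[k, 2]
      if (rr >= 1 && rr <= nrow(labels) && cc >= 1 && cc <= ncol(labels) &&
          !is.na(labels[rr, cc]) && !(labels[rr, cc] %in% lesion_ids)) {
        ok <- FALSE; break
      }
    }
    ok
  }, logical(1))
  mean(interior)
}

#' Generate a synthetic cohort
#'
#' Draws per-patient lesion burden, generates cores, and samples the
#' dichotomized outcome from the logistic model described in [cohort_spec()].
#' Simulated clinical values are back-filled to be consistent with the label:
#' label +1 implies eGFR at biopsy in \[60, 120\] and a nonnegative eGFR
#' slope over the following year; label -1 implies eGFR in \[15, 59\] and a
#' negative slope.
#'
#' @param spec a [cohort_spec()].
#' @param render generate pixel data (`TRUE`) or ground truth only.
#' @return list with `cores` (list of core image objects, see
#'   [core_image()]), `clinical` (tibble), `truth` (list: `patients` tibble
#'   with latent probability/draw/label, `core_labels` named list of lattice
#'   matrices, `core_info` tibble).
#' @export
generate_cohort <- function(spec, render = TRUE) {
  assert_that(inherits(spec, "cohort_spec"), "spec must be a cohort_spec")
  set.seed(derive_seed(spec$seed, "cohort"))
  cores <- list()
  core_labels <- list()
  core_rows <- list()
  pat_rows <- list()
  # pre-draw per-patient randomness so core generation order cannot drift
  n <- spec$n_patients
  u <- stats::runif(n)
  n_cores_all <- sample(seq(spec$cores_per_patient[1], spec$cores_per_patient[2]),
                        n, replace = TRUE)
  seed_draws <- stats::runif(n)  # label draws
  for (i in seq_len(n)) {
    pid <- sprintf("P%03d", i)
    fracs <- numeric(0); contigs <- numeric(0); nles <- numeric(0)
    for (j in seq_len(n_cores_all[i])) {
      cid <- sprintf("%s_C%d", pid, j)
      lf <- clamp(u[i] + stats::runif(1, -0.05, 0.05), 0, 1)
      core <- generate_synthetic_core(spec, lf,
                                      seed = derive_seed(spec$seed, pid, j),
                                      render = render)
      cores[[cid]] <- core_image(pid, cid,
                                 pixels = core$pixels,
                                 tissue_mask = core$tissue_mask)
      core_labels[[cid]] <- core$labels
      fracs <- c(fracs, core$lesion_fraction)
      contigs <- c(contigs, core$contiguity)
      nles <- c(nles, sum(!is.na(core$labels) &
                            core$labels %in% spec$lesion_pattern_ids))
      core_rows[[cid]] <- tibble(
        patient_id = pid, core_id = cid,
        tissue_area_px = sum(core$tissue_mask),
        lesion_fraction = core$lesion_fraction,
        contiguity = core$contiguity)
    }
    mean_frac <- mean(fracs)
    # patient contiguity: lesion-weighted mean over cores
    contig <- if (sum(nles) > 0) sum(contigs * nles) / sum(nles) else 0
    eta <- spec$intercept +
      spec$effect_size * (mean_frac - 0.5) +
      spec$spatial_effect * (contig - 0.5)
    p <- stats::plogis(eta)
    label <- if (seed_draws[i] < p) 1L else -1L
    pat_rows[[pid]] <- tibble(
      patient_id = pid, mean_lesion_fraction = mean_frac,
      contiguity = contig, latent_p = p, draw = seed_draws[i], label = label)
  }
  truth_patients <- dplyr::bind_rows(pat_rows)
  clinical <- simulate_clinical(truth_patients)
  list(spec = spec,
       cores = cores,
       clinical = clinical,
       truth = list(patients = truth_patients,
                    core_labels = core_labels,
                    core_info = dplyr::bind_rows(core_rows)))
}

#' Pixels of one cohort core, rendering on demand
#'
#' For cohorts generated with `render = FALSE` the pixel data of any core
#' can be regenerated deterministically from the cohort spec and the stored
#' realized lesion fraction, so large cohorts never need all cores in
#' memory at once.
#'
#' @param cohort result of [generate_cohort()].
#' @param core_id which core.
#' @return H x W x 3 pixel array on the 0..255 scale.
#' @export
cohort_core_pixels <- function(cohort, core_id) {
  core <- cohort$cores[[core_id]]
  assert_that(!is.null(core), paste0("unknown core ", core_id))
  if (!is.null(core$pixels)) return(core$pixels)
  info <- cohort$truth$core_info
  row <- info[info$core_id == core_id, ]
  j <- as.integer(sub(".*_C", "", core_id))
  regen <- generate_synthetic_core(
    cohort$spec, row$lesion_fraction,
    seed = derive_seed(cohort$spec$seed, core$patient_id, j), render = TRUE)
  regen$pixels
}

# Back-fill clinical values consistent with the dichotomized labels.
simulate_clinical <- function(truth_patients) {
  n <- nrow(truth_patients)
  lab <- truth_patients$label
  egfr <- ifelse(lab == 1L, stats::runif(n, 60, 120), stats::runif(n, 15, 59))
  age <- round(stats::runif(n, 25, 75))
  days0 <- age * 365L + sample(0:364, n, replace = TRUE)
  days1 <- days0 + 365L + sample(-30:30, n, replace = TRUE)
  gap <- days1 - days0
  slope <- ifelse(lab == 1L, stats::runif(n, 0, 0.02), stats::runif(n, -0.05, -0.002))
  egfr1 <- clamp(egfr + slope * gap, 5, 135)
  # keep the slope sign after clamping
  egfr1 <- ifelse(lab == 1L, pmax(egfr1, egfr), pmin(egfr1, egfr - 1e-6))
  tibble(
    patient_id = truth_patients$patient_id,
    age = age,
    gender = sample(c("F", "M"), n, replace = TRUE),
    race = sample(c("black", "white", "other"), n, replace = TRUE),
    diagnosis = sample(c("FSGS", "MCD", "IgA", "membranous", "other"),
                       n, replace = TRUE),
    egfr_biopsy = egfr,
    upc = stats::rlnorm(n, meanlog = ifelse(lab == 1L, -0.7, 0.3), sdlog = 0.6),
    egfr_year1 = egfr1,
    age_days_biopsy = days0,
    age_days_year1 = days1
  )
}

#' Write a synthetic cohort to disk
#'
#' Cores as PNG, clinical table and core manifest and per-patch ground truth
#' as CSV.
#'
#' @param cohort result of [generate_cohort()]; unrendered cohorts have
#'   their cores rendered one at a time while writing.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(file.path(dir, "cores"), recursive = TRUE, showWarnings = FALSE)
  for (core in cohort$cores) {
    png::writePNG(cohort_core_pixels(cohort, core$core_id) / 255,
                  file.path(dir, "cores", paste0(core$core_id, ".png")))
  }
  utils::write.csv(cohort$clinical, file.path(dir, "clinical.csv"), row.names = FALSE)
  utils::write.csv(cohort$truth$core_info, file.path(dir, "cores.csv"), row.names = FALSE)
  gt <- purrr::map(names(cohort$truth$core_labels), function(cid) {
    lab <- cohort$truth$core_labels[[cid]]
    idx <- which(!is.na(lab), arr.ind = TRUE)
    tibble(core_id = cid, row = idx[, 1], col = idx[, 2], pattern_id = lab[idx])
  })
  utils::write.csv(dplyr::bind_rows(gt), file.path(dir, "ground_truth.csv"),
                   row.names = FALSE)
  utils::write.csv(cohort$truth$patients, file.path(dir, "patients_truth.csv"),
                   row.names = FALSE)
  invisible(dir)
}
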