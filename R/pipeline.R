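#' Pipeline configuration
#'
#' A single structured configuration driving every stage; one global seed
#' deterministically derives all stage seeds.
#'
#' @param out_dir output directory for all stage artifacts.
#' @param images_dir directory of core PNG/TIFF files (defaults to the
#'   fixtures stage output).
#' @param clinical_csv clinical table path (defaults likewise).
#' @param cohort a [cohort_spec()] for the fixtures stage (optional when
#'   images are supplied externally).
#' @param patch_size,min_tissue_frac tiling parameters.
#' @param extractor feature extractor name.
#' @param k_range candidate cluster counts (lower bound 5 so the quartic
#'   trend is well-posed).
#' @param histogram_mode `"proportions"` or `"counts"`.
#' @param adjacency `"rook"` or `"queen"`.
#' @param dgcnn a [dgcnn_config()].
#' @param rf_ntree forest size.
#' @param task `"at_biopsy"` or `"one_year"`.
#' @param top_k features kept in the reduced model.
#' @param seed global seed.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(out_dir,
                            images_dir = NULL,
                            clinical_csv = NULL,
                            cohort = NULL,
                            patch_size = 32L,
                            min_tissue_frac = 0.5,
                            extractor = "texture",
                            k_range = 5:12,
                            histogram_mode = "proportions",
                            adjacency = "rook",
                            dgcnn = dgcnn_config(epochs = 40L, learning_rate = 1e-3, batch_size = 8L),
                            rf_ntree = 500L,
                            task = "at_biopsy",
                            top_k = 7L,
                            seed = 1L) {
  structure(
    list(out_dir = out_dir,
         images_dir = images_dir %||% file.path(out_dir, "data", "cores"),
         clinical_csv = clinical_csv %||% file.path(out_dir, "data", "clinical.csv"),
         cohort = cohort, patch_size = as.integer(patch_size),
         min_tissue_frac = min_tissue_frac, extractor = extractor,
         k_range = k_range, histogram_mode = histogram_mode,
         adjacency = adjacency, dgcnn = dgcnn, rf_ntree = as.integer(rf_ntree),
         task = task, top_k = as.integer(top_k), seed = as.integer(seed)),
    class = "pipeline_config"
  )
}

#' Read a pipeline configuration from YAML
#' @param path YAML file; fields as in [pipeline_config()].
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  y$dgcnn <- if (is.null(y$dgcnn)) dgcnn_config(epochs = 40L, learning_rate = 1e-3, batch_size = 8L)
             else do.call(dgcnn_config, y$dgcnn)
  if (!is.null(y$cohort)) y$cohort <- do.call(cohort_spec, y$cohort)
  do.call(pipeline_config, y)
}

.stage_order <- c("fixtures", "preprocess", "features", "cluster", "graphs",
                  "dgcnn", "awscore", "classify", "report")

stage_path <- function(config, ...) file.path(config$out_dir, ...)

require_artifact <- function(config, path, produced_by) {
  if (!file.exists(path)) {
    stop_input(sprintf("missing artifact '%s'; run stage '%s' first",
                       path, produced_by), "renograph_missing_stage")
  }
  path
}

write_manifest <- function(config, stage, inputs, outputs) {
  hashes <- tools::md5sum(inputs[file.exists(inputs)])
  jsonlite::write_json(
    list(stage = stage, inputs = as.list(hashes), outputs = outputs,
         seed = config$seed,
         version = as.character(utils::packageVersion("renograph"))),
    stage_path(config, paste0("manifest_", stage, ".json")),
    auto_unbox = TRUE)
}

#' Run one pipeline stage
#'
#' Stages (in order): fixtures, preprocess, features, cluster, graphs,
#' dgcnn, awscore, classify, report. Each stage reads only artifacts of its
#' upstream stages from `out_dir`, is deterministic given the configuration
#' seed, and records a manifest of input hashes.
#'
#' @param stage stage name.
#' @param config a [pipeline_config()].
#' @return invisibly, the stage's primary output path.
#' @export
run_stage <- function(stage, config) {
  stage <- match.arg(stage, .stage_order)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  out <- switch(stage,
    fixtures = stage_fixtures(config),
    preprocess = stage_preprocess(config),
    features = stage_features(config),
    cluster = stage_cluster(config),
    graphs = stage_graphs(config),
    dgcnn = stage_dgcnn(config),
    awscore = stage_awscore(config),
    classify = stage_classify(config),
    report = stage_report(config))
  invisible(out)
}

#' Run the full pipeline
#' @param config a [pipeline_config()].
#' @param stages stages to run, in order.
#' @export
run_pipeline <- function(config, stages = .stage_order) {
  for (s in stages) {
    message("[renograph] stage: ", s)
    run_stage(s, config)
  }
  invisible(config$out_dir)
}

stage_fixtures <- function(config) {
  assert_that(!is.null(config$cohort), "fixtures stage needs a cohort spec")
  cohort <- generate_cohort(config$cohort)
  dir <- stage_path(config, "data")
  write_cohort(cohort, dir)
  write_manifest(config, "fixtures", character(0), dir)
  dir
}

# Masks, pooled Lab reference statistics and the patch manifest. Pixel data
# are not persisted; the features stage re-reads and normalizes each core on
# the fly, keeping memory bounded.
stage_preprocess <- function(config) {
  manifest_csv <- require_artifact(config, file.path(dirname(config$clinical_csv),
                                                     "cores.csv"), "fixtures")
  cores_tbl <- utils::read.csv(manifest_csv)
  files <- file.path(config$images_dir, paste0(cores_tbl$core_id, ".png"))
  masks_area <- integer(nrow(cores_tbl))
  s1 <- s2 <- c(0, 0, 0); npx <- 0
  patch_rows <- list()
  for (i in seq_len(nrow(cores_tbl))) {
    core <- read_core_image(files[i], patient_id = cores_tbl$patient_id[i],
                            core_id = cores_tbl$core_id[i])
    core <- tissue_mask(core)
    masks_area[i] <- sum(core$tissue_mask)
    lab <- rgb_to_lab(pixel_matrix(core$pixels)[as.vector(core$tissue_mask), ,
                                                drop = FALSE])
    s1 <- s1 + colSums(lab); s2 <- s2 + colSums(lab^2); npx <- npx + nrow(lab)
    grid <- tile_core(core, config$patch_size, config$min_tissue_frac)
    patch_rows[[i]] <- dplyr::mutate(grid$entries, core_id = core$core_id,
                                     .before = 1)
  }
  mean <- s1 / npx
  sd <- sqrt(pmax(0, s2 / npx - mean^2))
  assert_that(all(sd > 1e-8), "degenerate pooled Lab statistics",
              "renograph_degenerate")
  stats <- structure(list(mean = mean, sd = sd, n_pixels = npx),
                     class = "lab_reference_stats")
  write_lab_stats(stats, stage_path(config, "lab_stats.json"))
  utils::write.csv(cbind(cores_tbl["core_id"], tissue_area_px = masks_area),
                   stage_path(config, "tissue_areas.csv"), row.names = FALSE)
  utils::write.csv(dplyr::bind_rows(patch_rows),
                   stage_path(config, "patch_manifest.csv"), row.names = FALSE)
  write_manifest(config, "preprocess", c(manifest_csv, files),
                 stage_path(config, "patch_manifest.csv"))
  stage_path(config, "patch_manifest.csv")
}

stage_features <- function(config) {
  stats_path <- require_artifact(config, stage_path(config, "lab_stats.json"),
                                 "preprocess")
  ref <- read_lab_stats(stats_path)
  cores_tbl <- utils::read.csv(file.path(dirname(config$clinical_csv), "cores.csv"))
  fms <- list()
  for (i in seq_len(nrow(cores_tbl))) {
    core <- read_core_image(file.path(config$images_dir,
                                      paste0(cores_tbl$core_id[i], ".png")),
                            patient_id = cores_tbl$patient_id[i],
                            core_id = cores_tbl$core_id[i])
    core <- tissue_mask(core)
    core <- reinhard_normalize(core, ref, mask = core$tissue_mask)
    grid <- tile_core(core, config$patch_size, config$min_tissue_frac)
    if (nrow(grid$entries) == 0) next
    fms[[length(fms) + 1]] <- extract_features(grid, config$extractor)
  }
  fm <- bind_features(fms)
  saveRDS(fm, stage_path(config, "features.rds"))
  write_manifest(config, "features", stats_path, stage_path(config, "features.rds"))
  stage_path(config, "features.rds")
}

stage_cluster <- function(config) {
  fpath <- require_artifact(config, stage_path(config, "features.rds"), "features")
  fm <- standardize_features(readRDS(fpath))
  k <- select_k_silhouette(fm, config$k_range, seed = derive_seed(config$seed, "k"))
  model <- fit_kmeans(fm, k, seed = derive_seed(config$seed, "km"))
  asg <- assign_clusters(fm, model)
  hists <- case_histogram(asg, model, mode = config$histogram_mode)
  polys <- poly4_table(case_histogram(asg, model, mode = "proportions"))
  write_cluster_model(model, stage_path(config, "cluster_model.json"))
  saveRDS(list(model = model, assignment = asg, standardize =
                 list(center = fm$center, scale = fm$scale)),
          stage_path(config, "clustering.rds"))
  utils::write.csv(hists, stage_path(config, "histograms.csv"), row.names = FALSE)
  utils::write.csv(polys, stage_path(config, "poly_coeffs.csv"), row.names = FALSE)
  write_manifest(config, "cluster", fpath, stage_path(config, "clustering.rds"))
  stage_path(config, "clustering.rds")
}

stage_graphs <- function(config) {
  cpath <- require_artifact(config, stage_path(config, "clustering.rds"), "cluster")
  cl <- readRDS(cpath)
  clinical <- utils::read.csv(config$clinical_csv)
  labels <- outcome_labels(clinical, config$task)
  lab_of <- stats::setNames(labels$label, labels$patient_id)
  gdir <- stage_path(config, "graphs")
  dir.create(gdir, showWarnings = FALSE)
  ids <- cl$assignment$ids
  rows <- list()
  for (cid in unique(ids$core_id)) {
    sel <- which(ids$core_id == cid)
    sub <- structure(list(ids = ids[sel, ], cluster = cl$assignment$cluster[sel],
                          distances = cl$assignment$distances[sel, , drop = FALSE]),
                     class = "cluster_assignment")
    lattice <- matrix(NA_integer_, max(sub$ids$row), max(sub$ids$col))
    lattice[cbind(sub$ids$row, sub$ids$col)] <- sub$cluster
    map <- structure(list(core_id = cid, patient_id = sub$ids$patient_id[1],
                          lattice = lattice, palette = cl$model$palette),
                     class = "cluster_map")
    g <- build_core_graph(map, cl$model, adjacency = config$adjacency,
                          label = lab_of[[map$patient_id]])
    path <- file.path(gdir, paste0(cid, ".graphml"))
    write_core_graph(g, path)
    png::writePNG(render_cluster_map(map),
                  file.path(gdir, paste0(cid, "_map.png")))
    rows[[cid]] <- tibble(core_id = cid, patient_id = map$patient_id,
                          graph_file = path, label = g$label,
                          n_nodes = nrow(g$nodes))
  }
  utils::write.csv(dplyr::bind_rows(rows), stage_path(config, "graph_manifest.csv"),
                   row.names = FALSE)
  write_manifest(config, "graphs", cpath, gdir)
  stage_path(config, "graph_manifest.csv")
}

stage_dgcnn <- function(config) {
  gman <- require_artifact(config, stage_path(config, "graph_manifest.csv"),
                           "graphs")
  man <- utils::read.csv(gman)
  graphs <- lapply(man$graph_file, read_core_graph)
  pat <- unique(tibble(patient_id = man$patient_id, label = as.integer(man$label)))
  plan <- make_fold_plan(pat, n_folds = 3L, seed = derive_seed(config$seed, "plan"))
  cfg <- config$dgcnn
  cfg$seed <- derive_seed(config$seed, "dgcnn")
  cv <- train_dgcnn(graphs, plan, cfg)
  saveRDS(cv, stage_path(config, "dgcnn.rds"))
  utils::write.csv(cv$oof, stage_path(config, "oof_predictions.csv"),
                   row.names = FALSE)
  write_manifest(config, "dgcnn", gman, stage_path(config, "oof_predictions.csv"))
  stage_path(config, "oof_predictions.csv")
}

stage_awscore <- function(config) {
  oof_path <- require_artifact(config, stage_path(config, "oof_predictions.csv"),
                               "dgcnn")
  areas_path <- require_artifact(config, stage_path(config, "tissue_areas.csv"),
                                 "preprocess")
  oof <- utils::read.csv(oof_path)
  areas <- normalize_areas(utils::read.csv(areas_path))
  merged <- dplyr::left_join(as_tibble(oof), as_tibble(areas), by = "core_id")
  scores <- patient_scores(dplyr::select(merged, "patient_id", "core_id",
                                         "area", "pred"))
  utils::write.csv(scores, stage_path(config, "patient_scores.csv"),
                   row.names = FALSE)
  write_manifest(config, "awscore", c(oof_path, areas_path),
                 stage_path(config, "patient_scores.csv"))
  stage_path(config, "patient_scores.csv")
}

stage_classify <- function(config) {
  spath <- require_artifact(config, stage_path(config, "patient_scores.csv"),
                            "awscore")
  hpath <- require_artifact(config, stage_path(config, "histograms.csv"),
                            "cluster")
  scores <- as_tibble(utils::read.csv(spath))
  hists <- as_tibble(utils::read.csv(hpath))
  polys <- as_tibble(utils::read.csv(stage_path(config, "poly_coeffs.csv")))
  clinical <- as_tibble(utils::read.csv(config$clinical_csv))
  features <- assemble_features(scores, hists, polys, clinical, config$task)
  full <- train_rf(features, ntree = config$rf_ntree,
                   seed = derive_seed(config$seed, "rf_full"))
  top <- select_top_k(full$ranking, min(config$top_k, nrow(full$ranking)))
  cv_all <- rf_cv_evaluate(features, ntree = config$rf_ntree,
                           seed = derive_seed(config$seed, "rf_cv"))
  cv_top <- rf_cv_evaluate(features, ntree = config$rf_ntree,
                           seed = derive_seed(config$seed, "rf_cv_top"),
                           columns = top)
  utils::write.csv(full$ranking, stage_path(config, "importance.csv"),
                   row.names = FALSE)
  utils::write.csv(features, stage_path(config, "patient_features.csv"),
                   row.names = FALSE)
  write_eval_report(cv_all$report, stage_path(config, "eval_all.json"))
  write_eval_report(cv_top$report, stage_path(config, "eval_top.json"))
  saveRDS(list(features = features, full = full, top = top, cv_all = cv_all,
               cv_top = cv_top),
          stage_path(config, "classify.rds"))
  write_manifest(config, "classify", c(spath, hpath), stage_path(config, "eval_top.json"))
  stage_path(config, "eval_top.json")
}

stage_report <- function(config) {
  cpath <- require_artifact(config, stage_path(config, "classify.rds"), "classify")
  res <- readRDS(cpath)
  rep <- res$cv_top$report
  jsonlite::write_json(
    list(task = config$task,
         oob_error = res$full$oob_error,
         top_features = res$top,
         auc = rep$auc, accuracy = rep$accuracy,
         sensitivity = rep$sensitivity, specificity = rep$specificity),
    stage_path(config, "report.json"), digits = NA, auto_unbox = TRUE)
  write_manifest(config, "report", cpath, stage_path(config, "report.json"))
  stage_path(config, "report.json")
}

#' End-to-end in-memory analysis of a synthetic cohort
#'
#' Runs the full method on an in-memory cohort without disk round-trips:
#' masking, pooled-Lab Reinhard normalization, tiling, feature extraction,
#' silhouette-selected clustering, histogram and quartic trend features,
#' graph construction, patient-stratified DGCNN cross-validation,
#' area-weighted patient scores, and the random forest evaluation (all
#' features and Gini top-k).
#'
#' @param cohort result of [generate_cohort()]; may be unrendered — cores
#'   are rendered on demand and discarded, keeping memory bounded.
#' @param config a [pipeline_config()] (`out_dir` unused here).
#' @return list: `features`, `model` (cluster model), `hists`, `polys`,
#'   `scores`, `dgcnn` (the CV object), `full_rf`, `top` (selected feature
#'   names), `cv_all`, `cv_top`.
#' @export
analyze_cohort <- function(cohort, config = pipeline_config(out_dir = tempfile())) {
  # pass 1 (streaming): masks and pooled Lab statistics, pixels discarded
  core_ids <- names(cohort$cores)
  masks <- list()
  s1 <- s2 <- c(0, 0, 0); npx <- 0
  for (cid in core_ids) {
    px <- cohort_core_pixels(cohort, cid)
    m <- tissue_mask(px)
    masks[[cid]] <- m
    lab <- rgb_to_lab(pixel_matrix(px)[as.vector(m), , drop = FALSE])
    s1 <- s1 + colSums(lab); s2 <- s2 + colSums(lab^2); npx <- npx + nrow(lab)
  }
  mu <- s1 / npx
  sg <- sqrt(pmax(0, s2 / npx - mu^2))
  assert_that(all(sg > 1e-8), "degenerate pooled Lab statistics",
              "renograph_degenerate")
  ref <- structure(list(mean = mu, sd = sg, n_pixels = npx),
                   class = "lab_reference_stats")
  # pass 2 (streaming): normalize, tile, extract features per core
  fms <- list()
  areas <- list()
  for (cid in core_ids) {
    meta <- cohort$cores[[cid]]
    core <- core_image(meta$patient_id, cid, cohort_core_pixels(cohort, cid),
                       tissue_mask = masks[[cid]])
    norm <- reinhard_normalize(core, ref, mask = core$tissue_mask)
    grid <- tile_core(norm, config$patch_size, config$min_tissue_frac)
    areas[[cid]] <- tibble(patient_id = core$patient_id, core_id = cid,
                           tissue_area_px = sum(core$tissue_mask))
    if (nrow(grid$entries) > 0) {
      fms[[cid]] <- extract_features(grid, config$extractor)
    }
  }
  masks <- NULL
  fm <- standardize_features(bind_features(fms))
  k <- select_k_silhouette(fm, config$k_range, seed = derive_seed(config$seed, "k"))
  model <- fit_kmeans(fm, k, seed = derive_seed(config$seed, "km"))
  asg <- assign_clusters(fm, model)
  hists <- case_histogram(asg, model, mode = config$histogram_mode)
  polys <- poly4_table(case_histogram(asg, model, mode = "proportions"))
  clinical <- cohort$clinical
  labels <- outcome_labels(clinical, config$task)
  lab_of <- stats::setNames(labels$label, labels$patient_id)
  graphs <- list()
  ids <- asg$ids
  for (cid in unique(ids$core_id)) {
    sel <- which(ids$core_id == cid)
    lattice <- matrix(NA_integer_, max(ids$row[sel]), max(ids$col[sel]))
    lattice[cbind(ids$row[sel], ids$col[sel])] <- asg$cluster[sel]
    map <- structure(list(core_id = cid, patient_id = ids$patient_id[sel][1],
                          lattice = lattice, palette = model$palette),
                     class = "cluster_map")
    graphs[[cid]] <- build_core_graph(map, model, adjacency = config$adjacency,
                                      label = lab_of[[map$patient_id]])
  }
  plan <- make_fold_plan(labels, n_folds = 3L,
                         seed = derive_seed(config$seed, "plan"))
  cfg <- config$dgcnn
  cfg$seed <- derive_seed(config$seed, "dgcnn")
  cv <- train_dgcnn(unname(graphs), plan, cfg)
  area_tbl <- normalize_areas(dplyr::bind_rows(areas))
  merged <- dplyr::left_join(cv$oof, dplyr::select(area_tbl, "core_id", "area"),
                             by = "core_id")
  scores <- patient_scores(dplyr::select(merged, "patient_id", "core_id",
                                         "area", "pred"))
  features <- assemble_features(scores, hists, polys, clinical, config$task)
  full <- train_rf(features, ntree = config$rf_ntree,
                   seed = derive_seed(config$seed, "rf_full"))
  top <- select_top_k(full$ranking, min(config$top_k, nrow(full$ranking)))
  cv_all <- rf_cv_evaluate(features, ntree = config$rf_ntree,
                           seed = derive_seed(config$seed, "rf_cv"))
  cv_top <- rf_cv_evaluate(features, ntree = config$rf_ntree,
                           seed = derive_seed(config$seed, "rf_cv_top"),
                           columns = top)
  list(features = features, model = model, hists = hists, polys = polys,
       scores = scores, graphs = graphs, dgcnn = cv, full_rf = full,
       top = top, cv_all = cv_all, cv_top = cv_top)
}
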