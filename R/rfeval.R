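#' eGFR slope over the year after biopsy
#'
#' `(eGFR at year 1 - eGFR at biopsy) / (age in days at year 1 - age in days
#' at biopsy)`, in eGFR units per day.
#'
#' @param egfr_biopsy,egfr_year1 eGFR values (mL/min/1.73m^2).
#' @param age_days_biopsy,age_days_year1 patient age in days at the two
#'   timepoints; the difference must be positive.
#' @return slope per day (vectorized).
#' @export
egfr_slope <- function(egfr_biopsy, egfr_year1, age_days_biopsy, age_days_year1) {
  gap <- age_days_year1 - age_days_biopsy
  assert_that(all(gap > 0), "age at year 1 must exceed age at biopsy",
              "renograph_domain")
  (egfr_year1 - egfr_biopsy) / gap
}

#' Dichotomized outcome labels
#'
#' At-biopsy task: +1 iff eGFR at biopsy >= 60. One-year task: +1 iff the
#' eGFR slope is nonnegative. The positive class is the preserved-function /
#' non-declining group in both tasks.
#'
#' @param clinical clinical tibble (columns per [generate_cohort()]).
#' @param task `"at_biopsy"` or `"one_year"`.
#' @return tibble: patient_id, label in `{-1, +1}`.
#' @export
outcome_labels <- function(clinical, task = c("at_biopsy", "one_year")) {
  task <- match.arg(task)
  lab <- if (task == "at_biopsy") {
    ifelse(clinical$egfr_biopsy >= 60, 1L, -1L)
  } else {
    sl <- egfr_slope(clinical$egfr_biopsy, clinical$egfr_year1,
                     clinical$age_days_biopsy, clinical$age_days_year1)
    ifelse(sl >= 0, 1L, -1L)
  }
  tibble(patient_id = clinical$patient_id, label = lab)
}

#' Assemble the patient feature table
#'
#' Joins the four feature groups — spatial (aw-score), cluster frequencies
#' f1..fK, quartic trend coefficients c1..c5, and clinical covariates — into
#' one row per patient. The one-year task additionally includes eGFR at
#' biopsy and UPC. Categorical clinical fields are integer-encoded with the
#' level dictionary persisted as an attribute; the feature-group map is
#' attached as the `groups` attribute.
#'
#' @param scores patient score tibble (from [patient_scores()]).
#' @param hists histogram tibble (from [case_histogram()]).
#' @param polys quartic coefficient tibble (from [poly4_table()]).
#' @param clinical clinical tibble.
#' @param task `"at_biopsy"` or `"one_year"`.
#' @return tibble: patient_id, label, then the feature columns in a fixed
#'   documented order (aw_score, f1..fK, c1..c5, clinical block).
#' @export
assemble_features <- function(scores, hists, polys, clinical,
                              task = c("at_biopsy", "one_year")) {
  task <- match.arg(task)
  pats <- unique(clinical$patient_id)
  for (src in list(scores = scores, hists = hists, polys = polys)) {
    miss <- setdiff(pats, src$patient_id)
    if (length(miss) > 0) {
      stop_input(paste0("patients missing from a feature source: ",
                        paste(miss, collapse = ", ")), "renograph_missing_patient")
    }
  }
  labels <- outcome_labels(clinical, task)
  enc <- list()
  clin <- tibble(patient_id = clinical$patient_id, age = as.numeric(clinical$age))
  for (v in c("gender", "race", "diagnosis")) {
    lev <- sort(unique(clinical[[v]]))
    enc[[v]] <- lev
    clin[[v]] <- as.integer(factor(clinical[[v]], levels = lev))
  }
  if (task == "one_year") {
    clin$egfr_biopsy <- clinical$egfr_biopsy
    clin$upc <- clinical$upc
  }
  fcols <- grep("^f\\d+$", names(hists), value = TRUE)
  out <- labels |>
    dplyr::left_join(dplyr::select(scores, "patient_id", aw_score = "total"),
                     by = "patient_id") |>
    dplyr::left_join(dplyr::select(hists, dplyr::all_of(c("patient_id", fcols))),
                     by = "patient_id") |>
    dplyr::left_join(dplyr::select(polys, "patient_id", paste0("c", 1:5)),
                     by = "patient_id") |>
    dplyr::left_join(clin, by = "patient_id")
  assert_that(!anyNA(out), "missing values after feature assembly")
  groups <- c(aw_score = "spatial",
              stats::setNames(rep("frequency", length(fcols)), fcols),
              stats::setNames(rep("coefficient", 5), paste0("c", 1:5)),
              stats::setNames(rep("clinical", ncol(clin) - 1),
                              setdiff(names(clin), "patient_id")))
  attr(out, "groups") <- groups
  attr(out, "encoding") <- enc
  out
}

feature_cols <- function(features) setdiff(names(features), c("patient_id", "label"))

#' Train the random forest classifier
#'
#' Seeded forest over the feature table with Gini (mean decrease in
#' impurity) importance ranking and the out-of-bag error.
#'
#' @param features feature tibble from [assemble_features()] (or any tibble
#'   with `patient_id`, `label` and numeric feature columns).
#' @param ntree number of trees.
#' @param seed integer seed.
#' @param columns optional subset of feature columns to use.
#' @return a `rf_model`: `fit` (randomForest object), `ranking` (tibble:
#'   feature, group, importance, rank), `oob_error`, `columns`.
#' @export
train_rf <- function(features, ntree = 500L, seed = 1L, columns = NULL) {
  cols <- columns %||% feature_cols(features)
  y <- factor(features$label, levels = c(-1, 1))
  assert_that(nlevels(droplevels(y)) == 2, "labels are single-class",
              "renograph_degenerate")
  x <- as.data.frame(features[, cols, drop = FALSE])
  assert_that(!anyNA(x), "missing values in features")
  set.seed(derive_seed(seed, "rf"))
  fit <- randomForest::randomForest(x = x, y = y, ntree = ntree,
                                    importance = FALSE)
  imp <- fit$importance[, "MeanDecreaseGini"]
  groups <- attr(features, "groups")
  ranking <- tibble(feature = names(imp),
                    group = if (is.null(groups)) NA_character_ else
                      unname(groups[names(imp)]),
                    importance = as.numeric(imp)) |>
    dplyr::arrange(dplyr::desc(.data$importance)) |>
    dplyr::mutate(rank = dplyr::row_number())
  structure(list(fit = fit, ranking = ranking,
                 oob_error = unname(fit$err.rate[ntree, "OOB"]),
                 columns = cols),
            class = "rf_model")
}

#' Select the top-k features by Gini importance
#'
#' Ties are resolved by the stable order of the ranking (original column
#' order among equals).
#'
#' @param ranking ranking tibble from [train_rf()] (already sorted), or an
#'   `rf_model`.
#' @param k number of features (1..nrow).
#' @return character vector of feature names.
#' @export
select_top_k <- function(ranking, k) {
  if (inherits(ranking, "rf_model")) ranking <- ranking$ranking
  assert_that(k >= 1, "k must be >= 1", "renograph_range")
  assert_that(k <= nrow(ranking), "k exceeds the number of features",
              "renograph_range")
  ranking$feature[seq_len(k)]
}

# ---- ROC / AUC -------------------------------------------------------------

# ROC points (FPR, TPR) over all score thresholds, descending, with the
# conventional (0,0) and (1,1) endpoints. Positive class is +1.
roc_points <- function(scores, labels) {
  pos <- labels == 1
  th <- sort(unique(scores), decreasing = TRUE)
  tpr <- vapply(th, function(t) mean(scores[pos] >= t), numeric(1))
  fpr <- vapply(th, function(t) mean(scores[!pos] >= t), numeric(1))
  tibble(threshold = c(Inf, th), fpr = c(0, fpr), tpr = c(0, tpr))
}

# Trapezoid AUC from ROC points.
trapezoid_auc <- function(roc) {
  sum(diff(roc$fpr) * (utils::head(roc$tpr, -1) + utils::tail(roc$tpr, -1)) / 2)
}

#' Evaluate out-of-sample scores against labels
#'
#' ROC curve from score thresholds, trapezoid AUC with a DeLong 95\%
#' confidence interval, and the confusion matrix at the 0.5 vote threshold
#' with the +1 (preserved-function / non-declining) class as positive.
#' Accuracy is `(TP + TN) / (TP + FN + TN + FP)`.
#'
#' @param scores numeric scores (e.g. out-of-fold +1 vote fractions).
#' @param labels true labels in `{-1, +1}`; both classes must be present.
#' @param threshold decision threshold on the score (default 0.5).
#' @return an `eval_report`: confusion counts, sensitivity, specificity,
#'   accuracy, `roc` (tibble), `auc`, `ci95`.
#' @export
evaluate_scores <- function(scores, labels, threshold = 0.5) {
  assert_that(length(scores) == length(labels), "scores and labels differ in length")
  assert_that(all(labels %in% c(-1, 1)), "labels must be -1 or +1")
  if (length(unique(labels)) < 2) {
    stop_input("evaluation needs both classes present", "renograph_evaluation")
  }
  pred <- ifelse(scores >= threshold, 1L, -1L)
  tp <- sum(pred == 1 & labels == 1)
  fn <- sum(pred == -1 & labels == 1)
  tn <- sum(pred == -1 & labels == -1)
  fp <- sum(pred == 1 & labels == -1)
  roc <- roc_points(scores, labels)
  auc <- trapezoid_auc(roc)
  ci <- tryCatch({
    r <- pROC::roc(response = labels, predictor = scores, levels = c(-1, 1),
                   direction = "<", quiet = TRUE)
    suppressWarnings(as.numeric(pROC::ci.auc(r, method = "delong"))[c(1, 3)])
  }, error = function(e) c(NA_real_, NA_real_))
  structure(
    list(tp = tp, fn = fn, tn = tn, fp = fp,
         sensitivity = tp / (tp + fn),
         specificity = tn / (tn + fp),
         accuracy = (tp + tn) / (tp + fn + tn + fp),
         roc = roc, auc = auc, ci95 = ci),
    class = "eval_report"
  )
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("<eval_report> acc %.3f | sens %.3f | spec %.3f | AUC %.3f (95%% CI %.3f-%.3f)\n",
              x$accuracy, x$sensitivity, x$specificity, x$auc,
              x$ci95[1], x$ci95[2]))
  cat(sprintf("  confusion: TP=%d FN=%d TN=%d FP=%d\n", x$tp, x$fn, x$tn, x$fp))
  invisible(x)
}

#' Patient-stratified cross-validated random forest evaluation
#'
#' Trains a forest per fold on the out-of-fold patients, scores the held-out
#' patients by their +1 vote fraction, and evaluates the pooled
#' out-of-sample scores.
#'
#' @param features feature tibble from [assemble_features()].
#' @param n_folds folds (default 3).
#' @param ntree trees per fold.
#' @param seed integer seed.
#' @param columns optional feature subset (e.g. the Gini top 7).
#' @return list: `report` (an `eval_report`), `scores` tibble (patient_id,
#'   fold, score, label), `plan`.
#' @export
rf_cv_evaluate <- function(features, n_folds = 3L, ntree = 500L, seed = 1L,
                           columns = NULL) {
  cols <- columns %||% feature_cols(features)
  plan <- make_fold_plan(dplyr::select(features, "patient_id", "label"),
                         n_folds = n_folds, seed = seed)
  fold_of <- stats::setNames(plan$assignment$fold, plan$assignment$patient_id)
  rows <- list()
  for (f in seq_len(n_folds)) {
    tr <- features[fold_of[features$patient_id] != f, , drop = FALSE]
    te <- features[fold_of[features$patient_id] == f, , drop = FALSE]
    attr(tr, "groups") <- attr(features, "groups")
    model <- train_rf(tr, ntree = ntree, seed = derive_seed(seed, "rfcv", f),
                      columns = cols)
    votes <- stats::predict(model$fit,
                            newdata = as.data.frame(te[, cols, drop = FALSE]),
                            type = "vote")
    rows[[f]] <- tibble(patient_id = te$patient_id, fold = f,
                        score = as.numeric(votes[, "1"]), label = te$label)
  }
  scores <- dplyr::bind_rows(rows)
  list(report = evaluate_scores(scores$score, scores$label),
       scores = scores, plan = plan)
}

#' Write an evaluation report to JSON (+ ROC points CSV)
#' @param report an `eval_report`.
#' @param path JSON path; ROC points go to `paste0(path, "_roc.csv")`.
#' @export
write_eval_report <- function(report, path) {
  jsonlite::write_json(
    list(confusion = list(tp = report$tp, fn = report$fn, tn = report$tn,
                          fp = report$fp),
         sensitivity = report$sensitivity, specificity = report$specificity,
         accuracy = report$accuracy, auc = report$auc, ci95 = report$ci95),
    path, digits = NA, auto_unbox = TRUE)
  utils::write.csv(report$roc, paste0(tools::file_path_sans_ext(path), "_roc.csv"),
                   row.names = FALSE)
  invisible(path)
}
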