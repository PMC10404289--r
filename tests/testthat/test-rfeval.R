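test_that("eGFR slope arithmetic and labels follow the definitions", {
  # equal eGFRs: slope 0, one-year label +1 by the >= 0 rule
  expect_equal(egfr_slope(80, 80, 10000, 10365), 0)
  clin0 <- tibble::tibble(patient_id = "a", egfr_biopsy = 80, egfr_year1 = 80,
                          age_days_biopsy = 10000, age_days_year1 = 10365)
  expect_equal(outcome_labels(clin0, "one_year")$label, 1L)

  # 80 -> 70 over 365 days
  s <- egfr_slope(80, 70, 20000, 20365)
  expect_equal(s, -10 / 365)
  # doubling the day gap halves the slope
  expect_equal(egfr_slope(80, 70, 20000, 20730), s / 2)
  expect_error(egfr_slope(80, 70, 20000, 20000), class = "renograph_domain")

  clin <- tibble::tibble(patient_id = c("a", "b", "c"),
                         egfr_biopsy = c(60, 59.9, 95),
                         egfr_year1 = c(55, 70, 100),
                         age_days_biopsy = rep(20000, 3),
                         age_days_year1 = rep(20365, 3))
  expect_equal(outcome_labels(clin, "at_biopsy")$label, c(1L, -1L, 1L))
  expect_equal(outcome_labels(clin, "one_year")$label, c(-1L, 1L, 1L))
})

make_sources <- function(n = 10, k = 9, seed = 1) {
  set.seed(seed)
  pid <- sprintf("p%02d", seq_len(n))
  scores <- tibble::tibble(patient_id = pid, n_cores = 2L,
                           total = runif(n, -1, 1),
                           class = 1L)
  hists <- tibble::as_tibble(
    cbind(data.frame(patient_id = pid),
          matrix(runif(n * k), n, k, dimnames = list(NULL, paste0("f", 1:k))),
          data.frame(total_patches = 50L)))
  polys <- tibble::as_tibble(
    cbind(data.frame(patient_id = pid),
          matrix(rnorm(n * 5), n, 5, dimnames = list(NULL, paste0("c", 1:5)))))
  clinical <- tibble::tibble(
    patient_id = pid, age = sample(30:70, n, TRUE),
    gender = sample(c("F", "M"), n, TRUE),
    race = sample(c("black", "white"), n, TRUE),
    diagnosis = sample(c("FSGS", "IgA"), n, TRUE),
    egfr_biopsy = runif(n, 20, 110), upc = runif(n, 0.1, 3),
    egfr_year1 = runif(n, 20, 110),
    age_days_biopsy = 15000L, age_days_year1 = 15365L)
  list(scores = scores, hists = hists, polys = polys, clinical = clinical)
}

test_that("feature assembly yields the documented inventory per task", {
  src <- make_sources(n = 8, k = 9, seed = 3)
  at <- assemble_features(src$scores, src$hists, src$polys, src$clinical,
                          "at_biopsy")
  # 1 aw-score + 9 frequencies + 5 coefficients + 4 clinical = 19 features
  fc <- setdiff(names(at), c("patient_id", "label"))
  expect_length(fc, 19)
  oy <- assemble_features(src$scores, src$hists, src$polys, src$clinical,
                          "one_year")
  expect_length(setdiff(names(oy), c("patient_id", "label")), 21)
  expect_true(all(c("egfr_biopsy", "upc") %in% names(oy)))
  # group tags cover every feature
  expect_setequal(names(attr(at, "groups")), fc)
  # categorical encoding is integer with a persisted dictionary
  expect_true(is.integer(at$gender))
  expect_named(attr(at, "encoding"), c("gender", "race", "diagnosis"))
  # identical inputs give identical rows
  src2 <- src
  src2$clinical$patient_id[1] <- "zz"
  expect_error(assemble_features(src$scores, src$hists, src$polys,
                                 src2$clinical, "at_biopsy"),
               class = "renograph_missing_patient")
})

test_that("random forests find planted signal and stay at chance on noise", {
  set.seed(5)
  n <- 200
  x <- matrix(rnorm(n * 8), n, 8, dimnames = list(NULL, paste0("v", 1:8)))
  label <- ifelse(x[, 3] > 0, 1L, -1L)
  feats <- tibble::as_tibble(cbind(
    data.frame(patient_id = sprintf("p%03d", 1:n), label = label), x))
  rf <- train_rf(feats, ntree = 300, seed = 7)
  expect_equal(rf$ranking$feature[1], "v3")
  expect_lte(rf$oob_error, 0.05)
  # determinism
  rf2 <- train_rf(feats, ntree = 300, seed = 7)
  expect_identical(rf$ranking, rf2$ranking)
  expect_identical(rf$oob_error, rf2$oob_error)

  # pure noise labels: OOB error within 3 binomial SDs of 0.5
  noise <- feats
  noise$label <- sample(c(-1L, 1L), n, replace = TRUE)
  rfn <- train_rf(noise, ntree = 300, seed = 11)
  expect_lt(abs(rfn$oob_error - 0.5), 3 * sqrt(0.25 / n))

  single <- feats; single$label <- 1L
  expect_error(train_rf(single), class = "renograph_degenerate")
})

test_that("top-k selection is rank-faithful and planted signals surface", {
  set.seed(13)
  ranking <- tibble::tibble(feature = paste0("v", 1:10), group = "g",
                            importance = 10:1, rank = 1:10)
  expect_equal(select_top_k(ranking, 10), paste0("v", 1:10))
  expect_equal(select_top_k(ranking, 7), paste0("v", 1:7))
  expect_error(select_top_k(ranking, 0), class = "renograph_range")
  expect_error(select_top_k(ranking, 11), class = "renograph_range")

  # three planted signals land inside the top 7 in >= 95% of replicates
  hits <- vapply(1:40, function(r) {
    set.seed(100 + r)
    n <- 120
    x <- matrix(rnorm(n * 12), n, 12, dimnames = list(NULL, paste0("v", 1:12)))
    score <- x[, 1] + x[, 2] - x[, 3] + rnorm(n, sd = 0.5)
    feats <- tibble::as_tibble(cbind(
      data.frame(patient_id = sprintf("p%03d", 1:n),
                 label = ifelse(score > 0, 1L, -1L)), x))
    rf <- train_rf(feats, ntree = 200, seed = r)
    all(c("v1", "v2", "v3") %in% select_top_k(rf$ranking, 7))
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("evaluation reproduces closed-form metrics and ROC conventions", {
  # perfect scores
  perfect <- evaluate_scores(c(0.9, 0.8, 0.2, 0.1), c(1, 1, -1, -1))
  expect_equal(perfect$auc, 1)
  expect_equal(perfect$accuracy, 1)

  # constant scores: AUC exactly 0.5 under the midpoint/trapezoid convention
  flat <- evaluate_scores(rep(0.7, 10), rep(c(1, -1), 5))
  expect_equal(flat$auc, 0.5)

  # Eq-identity: accuracy always equals (TP+TN)/(TP+FN+TN+FP)
  set.seed(17)
  sc <- runif(40); lb <- sample(c(-1, 1), 40, replace = TRUE)
  r <- evaluate_scores(sc, lb)
  expect_equal(r$accuracy, (r$tp + r$tn) / (r$tp + r$fn + r$tn + r$fp))
  # ROC is monotone nondecreasing and the CI brackets the AUC
  expect_true(all(diff(r$roc$tpr) >= 0) && all(diff(r$roc$fpr) >= 0))
  expect_true(r$ci95[1] <= r$auc && r$auc <= r$ci95[2])

  expect_error(evaluate_scores(sc, rep(1, 40)), class = "renograph_evaluation")
})

test_that("trapezoid AUC equals the Mann-Whitney statistic", {
  set.seed(19)
  for (i in 1:10) {
    n <- 30
    lb <- sample(c(-1, 1), n, replace = TRUE, prob = c(0.4, 0.6))
    if (length(unique(lb)) < 2) next
    sc <- round(runif(n), 2)  # force ties
    r <- evaluate_scores(sc, lb)
    pos <- sc[lb == 1]; neg <- sc[lb == -1]
    u <- sum(vapply(pos, function(p) sum(p > neg) + 0.5 * sum(p == neg),
                    numeric(1)))
    expect_equal(r$auc, u / (length(pos) * length(neg)), tolerance = 1e-10)
  }
})

test_that("cross-validated forest evaluation is patient-stratified and seeded", {
  set.seed(23)
  n <- 60
  x <- matrix(rnorm(n * 6), n, 6, dimnames = list(NULL, paste0("v", 1:6)))
  label <- ifelse(x[, 1] + rnorm(n, sd = 0.6) > 0, 1L, -1L)
  feats <- tibble::as_tibble(cbind(
    data.frame(patient_id = sprintf("p%03d", 1:n), label = label), x))
  cv <- rf_cv_evaluate(feats, ntree = 200, seed = 3)
  expect_setequal(cv$scores$patient_id, feats$patient_id)
  expect_gt(cv$report$auc, 0.7)
  cv2 <- rf_cv_evaluate(feats, ntree = 200, seed = 3)
  expect_identical(cv$scores, cv2$scores)
  # feature subsetting restricts the model to the given columns
  cv_sub <- rf_cv_evaluate(feats, ntree = 100, seed = 3, columns = c("v1", "v2"))
  expect_s3_class(cv_sub$report, "eval_report")
})
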