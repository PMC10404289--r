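#' Normalize core tissue areas across a cohort
#'
#' Each core's normalized area is its tissue-mask pixel count divided by the
#' largest tissue area in the cohort, so the largest core gets A = 1.
#'
#' @param cores tibble with at least `core_id` and `tissue_area_px` (> 0).
#' @return the tibble with a normalized `area` column in (0, 1].
#' @export
normalize_areas <- function(cores) {
  assert_that(nrow(cores) > 0, "empty cohort", "renograph_empty")
  assert_that(all(cores$tissue_area_px > 0), "tissue areas must be positive")
  dplyr::mutate(cores, area = .data$tissue_area_px / max(.data$tissue_area_px))
}

#' Area-weighted score of one core
#'
#' `aw = A * P`: the normalized core area signed by the core-level class
#' prediction.
#'
#' @param area normalized area in (0, 1].
#' @param pred predicted class, -1 or +1.
#' @return the aw-score.
#' @export
aw_score <- function(area, pred) {
  assert_that(all(pred %in% c(-1, 1)), "predictions must be -1 or +1",
              "renograph_domain")
  assert_that(all(area > 0 & area <= 1), "areas must lie in (0, 1]",
              "renograph_domain")
  area * pred
}

#' Patient-level area-weighted score
#'
#' Sums the aw-scores of one patient's cores; the patient class is +1 when
#' the total is nonnegative, -1 otherwise. The total is bounded by the sum
#' of areas, with equality exactly when all core predictions agree.
#'
#' @param core_preds tibble with `patient_id`, `core_id`, `area`, `pred`
#'   for the cores of a single patient.
#' @return one-row tibble: patient_id, n_cores, total (the summed aw-score),
#'   class.
#' @export
patient_score <- function(core_preds) {
  assert_that(nrow(core_preds) >= 1, "need at least one core", "renograph_empty")
  assert_that(length(unique(core_preds$patient_id)) == 1,
              "cores from more than one patient", "renograph_consistency")
  total <- sum(aw_score(core_preds$area, core_preds$pred))
  tibble(patient_id = core_preds$patient_id[1],
         n_cores = nrow(core_preds),
         total = total,
         class = if (total >= 0) 1L else -1L)
}

#' Patient-level scores for a whole cohort
#'
#' @param core_preds tibble with `patient_id`, `core_id`, `area`, `pred`
#'   covering every core of every patient.
#' @return tibble with one row per patient (see [patient_score()]).
#' @export
patient_scores <- function(core_preds) {
  dplyr::bind_rows(lapply(split(core_preds, core_preds$patient_id), patient_score))
}

#' Published aw-score worked examples
#'
#' The per-core normalized areas, core-level class predictions and printed
#' patient totals of the two published worked-example tables (at-biopsy and
#' one-year cross-validation), shipped as plain-text fixtures. A handful of
#' printed totals differ from the sum of their printed terms by one unit in
#' the second decimal (display rounding of the areas); `consistent` flags
#' rows whose printed total matches the arithmetic exactly.
#'
#' @param table `"at_biopsy"` (Table of the biopsy task) or `"one_year"`.
#' @return tibble: case_id, fold_group, core_idx, area, pred, printed_total,
#'   consistent.
#' @export
awscore_examples <- function(table = c("at_biopsy", "one_year")) {
  table <- match.arg(table)
  file <- if (table == "at_biopsy") "awscore_table2.csv" else "awscore_table3.csv"
  raw <- utils::read.csv(system.file("extdata", file, package = "renograph"),
                         stringsAsFactors = FALSE)
  rows <- purrr::map(seq_len(nrow(raw)), function(i) {
    a <- as.numeric(strsplit(raw$areas[i], ";")[[1]])
    p <- as.integer(strsplit(raw$preds[i], ";")[[1]])
    tibble(case_id = raw$case_id[i], fold_group = raw$fold_group[i],
           core_idx = seq_along(a), area = a, pred = p,
           printed_total = raw$printed_total[i])
  })
  out <- dplyr::bind_rows(rows)
  cons <- out |>
    dplyr::group_by(.data$case_id) |>
    dplyr::summarise(consistent = abs(sum(.data$area * .data$pred) -
                                        .data$printed_total[1]) < 0.005)
  dplyr::left_join(out, cons, by = "case_id")
}
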