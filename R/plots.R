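#' Plot a case histogram with its quartic trend
#'
#' Bars are the MDS-ordered cluster frequencies of one case; the curve is
#' the fitted quartic trend whose coefficients feed the classifier.
#'
#' @param hists histogram tibble from [case_histogram()].
#' @param patient_id which case to plot (default: the first).
#' @param model optional `cluster_model` supplying bar colours.
#' @return a ggplot object.
#' @export
plot_case_histogram <- function(hists, patient_id = hists$patient_id[1],
                                model = NULL) {
  row <- hists[hists$patient_id == patient_id, ]
  assert_that(nrow(row) == 1, "patient not found in histogram table")
  fcols <- grep("^f\\d+$", names(row), value = TRUE)
  f <- as.numeric(row[1, fcols])
  df <- tibble(bin = seq_along(f), frequency = f)
  cc <- fit_poly4(f)
  xs <- seq(1, length(f), length.out = 200)
  trend <- tibble(bin = xs,
                  frequency = cc[1] * xs^4 + cc[2] * xs^3 + cc[3] * xs^2 +
                    cc[4] * xs + cc[5])
  fill <- if (is.null(model)) "grey40" else model$palette[model$mds_order]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$bin, y = .data$frequency)) +
    ggplot2::geom_col(fill = fill, colour = "grey20") +
    ggplot2::geom_line(data = trend, colour = "red", linewidth = 0.8) +
    ggplot2::scale_x_continuous(breaks = df$bin,
                                labels = paste0("f", df$bin)) +
    ggplot2::labs(title = paste("Cluster histogram:", patient_id),
                  x = "visual pattern (MDS order)", y = "frequency") +
    ggplot2::theme_minimal()
}

#' Plot a colour-coded cluster map
#'
#' @param map a `cluster_map`.
#' @return a ggplot object (tile raster of the lattice).
#' @export
plot_cluster_map <- function(map) {
  lat <- map$lattice
  idx <- which(!is.na(lat), arr.ind = TRUE)
  df <- tibble(row = idx[, 1], col = idx[, 2],
               cluster = factor(lat[idx]))
  pal <- stats::setNames(map$palette[as.integer(levels(df$cluster))],
                         levels(df$cluster))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row,
                                   fill = .data$cluster)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_manual(values = pal) +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_equal() +
    ggplot2::labs(title = paste("Cluster map:", map$core_id)) +
    ggplot2::theme_void() +
    ggplot2::theme(legend.position = "right")
}

#' Plot an ROC curve
#'
#' @param report an `eval_report` from [evaluate_scores()].
#' @return a ggplot object.
#' @export
plot_roc <- function(report) {
  ggplot2::ggplot(report$roc, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::geom_step(colour = "#1F77B4", linewidth = 0.9) +
    ggplot2::coord_equal() +
    ggplot2::labs(title = sprintf("ROC (AUC = %.3f)", report$auc),
                  x = "false positive rate", y = "true positive rate") +
    ggplot2::theme_minimal()
}

#' Plot the Gini importance ranking
#'
#' @param ranking ranking tibble from [train_rf()] (or an `rf_model`).
#' @param top_n show the top n features.
#' @return a ggplot object.
#' @export
plot_importance <- function(ranking, top_n = 15L) {
  if (inherits(ranking, "rf_model")) ranking <- ranking$ranking
  df <- utils::head(ranking, top_n)
  df$feature <- factor(df$feature, levels = rev(df$feature))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$importance, y = .data$feature,
                                   fill = .data$group)) +
    ggplot2::geom_col() +
    ggplot2::labs(title = "Gini importance", x = "mean decrease in Gini impurity",
                  y = NULL, fill = "feature group") +
    ggplot2::theme_minimal()
}
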