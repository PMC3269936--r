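# ggplot2 views of the main result types.

#' Interpolated precision/recall curve
#'
#' Plots precision against recall over the pooled ranked prediction list,
#' with the interpolated (monotone) envelope that the AUC iP/R integrates.
#'
#' @param predictions tibble `doc_id`, `method_id`, `confidence`.
#' @param gold tibble `doc_id`, `method_id`.
#' @return a ggplot object.
#' @export
plot_ipr_curve <- function(predictions, gold) {
  g <- dplyr::distinct(gold[, c("doc_id", "method_id")])
  p <- predictions |>
    dplyr::arrange(dplyr::desc(.data$confidence), .data$method_id,
                   .data$doc_id)
  is_hit <- paste(p$doc_id, p$method_id) %in% paste(g$doc_id, g$method_id)
  ranks <- seq_along(is_hit)
  df <- tibble::tibble(
    recall = cumsum(is_hit) / nrow(g),
    precision = cumsum(is_hit) / ranks
  )
  df$interpolated <- rev(cummax(rev(df$precision)))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$recall)) +
    ggplot2::geom_step(ggplot2::aes(y = .data$precision),
                       colour = "grey60") +
    ggplot2::geom_step(ggplot2::aes(y = .data$interpolated),
                       colour = "#2166ac", linewidth = 0.8) +
    ggplot2::coord_cartesian(xlim = c(0, 1), ylim = c(0, 1)) +
    ggplot2::labs(x = "Recall", y = "Precision",
                  title = "Interpolated precision/recall curve") +
    ggplot2::theme_minimal()
}

#' Metric as a function of the discretization threshold
#'
#' Shows how MCC (or F-score / accuracy) varies with the DTH on labelled
#' classifier values; the view used to pick a DTH on a development set.
#'
#' @param values classifier values.
#' @param labels 0/1 gold labels.
#' @param criterion `"mcc"`, `"fscore"` or `"accuracy"`.
#' @param grid_step threshold grid resolution.
#' @return a ggplot object.
#' @export
plot_dth_curve <- function(values, labels, criterion = "mcc",
                           grid_step = 0.01) {
  grid <- seq(grid_step, 1 - grid_step, by = grid_step)
  crit <- vapply(grid, function(dth) {
    cc <- confusion_binary(as.integer(values >= dth), labels)
    switch(criterion,
           mcc = mcc(cc),
           fscore = {
             f <- basic_metrics(cc)$f_score
             if (is.na(f)) 0 else f
           },
           accuracy = basic_metrics(cc)$accuracy)
  }, numeric(1))
  df <- tibble::tibble(dth = grid, metric = crit)
  best <- df$dth[which.max(df$metric)]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$dth, y = .data$metric)) +
    ggplot2::geom_line(colour = "#2166ac") +
    ggplot2::geom_vline(xintercept = best, linetype = "dashed",
                        colour = "grey40") +
    ggplot2::labs(x = "Discretization threshold (DTH)", y = criterion,
                  title = "Metric vs discretization threshold") +
    ggplot2::theme_minimal()
}

#' Plot per-fold cross-validation metrics
#'
#' @param cv_results a tibble from [act_cv()].
#' @param metrics which metric columns to show.
#' @return a ggplot object.
#' @export
plot_cv_metrics <- function(cv_results,
                            metrics = c("mcc", "f_score", "auc_ipr")) {
  long <- tidyr::pivot_longer(
    cv_results[, c("fold", metrics)],
    dplyr::all_of(metrics), names_to = "metric", values_to = "value"
  )
  ggplot2::ggplot(long, ggplot2::aes(x = .data$metric, y = .data$value)) +
    ggplot2::geom_boxplot(fill = "grey90", outlier.shape = NA) +
    ggplot2::geom_jitter(width = 0.1, alpha = 0.6, colour = "#2166ac") +
    ggplot2::labs(x = NULL, y = "Per-fold value",
                  title = "Cross-validation metrics") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Weight profile of a fitted maximum-entropy model
#'
#' @param object a `cm_maxent` model.
#' @param n_top number of largest-magnitude features to display.
#' @param ... unused.
#' @return a ggplot object.
#' @method autoplot cm_maxent
#' @export
autoplot.cm_maxent <- function(object, n_top = 30L, ...) {
  td <- tidy(object)
  td <- td[td$term != "(bias)", , drop = FALSE]
  td <- utils::head(td, n_top)
  td$term <- factor(td$term, levels = rev(td$term))
  ggplot2::ggplot(td, ggplot2::aes(x = .data$estimate, y = .data$term)) +
    ggplot2::geom_col(fill = "#2166ac") +
    ggplot2::labs(x = "Weight", y = NULL,
                  title = "Largest maximum-entropy feature weights") +
    ggplot2::theme_minimal()
}
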