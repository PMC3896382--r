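#' Plot predictor weights of a fitted model
#'
#' Diverging bar chart of the model's predictors ordered by weight — the
#' point of the method is that this list is directly interpretable: a user
#' can read off which subsequences argue for and against class membership.
#'
#' @param object An `slr_model`.
#' @param top Show at most this many predictors by absolute weight.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.slr_model <- function(object, top = 30, ...) {
  d <- object$predictors |>
    dplyr::arrange(dplyr::desc(abs(.data$weight))) |>
    utils::head(top) |>
    dplyr::mutate(subseq = stats::reorder(.data$subseq, .data$weight),
                  sign = ifelse(.data$weight >= 0, "positive", "negative"))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$weight, y = .data$subseq,
                                  fill = .data$sign)) +
    ggplot2::geom_col(show.legend = FALSE) +
    ggplot2::labs(x = "weight", y = "predictor subsequence",
                  title = if (!is.na(object$class_label))
                    paste("SLR predictors, class", object$class_label)
                  else "SLR predictors") +
    ggplot2::theme_minimal()
}

#' ROC curve of a cross-validation run
#'
#' Step curve over the pooled held-out scores, with the pooled AUC in the
#' subtitle.
#'
#' @param object An `slr_cv` object from [cross_validate()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.slr_cv <- function(object, ...) {
  s <- object$scores
  y <- label_to_y(s$label)
  ord <- order(s$score, decreasing = TRUE)
  tpr <- cumsum(y[ord] > 0) / sum(y > 0)
  fpr <- cumsum(y[ord] < 0) / sum(y < 0)
  d <- tibble::tibble(fpr = c(0, fpr), tpr = c(0, tpr))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_step() +
    ggplot2::geom_abline(linetype = "dotted") +
    ggplot2::labs(x = "false-positive rate", y = "true-positive rate",
                  title = sprintf("%d-fold cross-validation ROC", object$k),
                  subtitle = sprintf("pooled AUC = %.4f", object$pooled$auc)) +
    ggplot2::theme_minimal()
}

#' Plot assigned-class counts of a classification run
#'
#' @param records Tibble from [classify_sequences()].
#' @param class_list Display order, default [ptype_classes()] with the
#'   rejection class `"0"` first.
#' @return A ggplot object.
#' @export
plot_class_counts <- function(records, class_list = ptype_classes()) {
  d <- records |>
    dplyr::count(assigned = factor(.data$assigned,
                                   levels = c("0", class_list)))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$assigned, y = .data$n)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "assigned class", y = "sequences") +
    ggplot2::theme_minimal()
}

#' Heatmap of the category-by-class topology summary
#'
#' @param summary Tibble from [topology_summary()].
#' @return A ggplot object.
#' @export
plot_topology_summary <- function(summary) {
  d <- summary |>
    dplyr::filter(.data$class != "Total") |>
    tidyr::pivot_longer(dplyr::all_of(topology_categories()),
                        names_to = "category", values_to = "n") |>
    dplyr::mutate(category = factor(.data$category,
                                    levels = topology_categories()),
                  class = factor(.data$class, levels = rev(unique(.data$class))))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$category, y = .data$class,
                                  fill = .data$n)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = .data$n), size = 3) +
    ggplot2::scale_fill_gradient(low = "white", high = "steelblue") +
    ggplot2::labs(x = "topology category", y = "class", fill = "count") +
    ggplot2::theme_minimal()
}
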