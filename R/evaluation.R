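#' Stratified k-fold assignment
#'
#' Partitions the data into `k` folds. With `stratify = TRUE` (the
#' default) the shuffle happens within each label group and members are
#' dealt round-robin, so per-fold counts of any label differ by at most
#' one — essential when a few hundred positives sit in tens of thousands
#' of negatives, where an unstratified fold can easily contain no positive
#' at all. Shuffling is driven only by `seed`.
#'
#' @param data Sequence tibble with a `label` column.
#' @param k Number of folds.
#' @param seed Integer seed.
#' @param stratify Stratify by label (default `TRUE`).
#' @return `data` with an integer `fold` column (1..k) appended.
#' @export
kfold_split <- function(data, k = 10, seed = 1, stratify = TRUE) {
  n <- nrow(data)
  if (n < k) abort("fewer sequences than folds")
  fold <- integer(n)
  withr::with_seed(seed, {
    if (stratify) {
      counts <- table(data$label)
      if (any(counts < k)) {
        abort(paste0("label group(s) smaller than k = ", k, ": ",
                     paste(names(counts)[counts < k], collapse = ", "),
                     "; use stratify = FALSE to allow this"))
      }
      for (lab in names(counts)) {
        idx <- sample(which(data$label == lab))
        fold[idx] <- rep_len(seq_len(k), length(idx))
      }
    } else {
      fold[sample.int(n)] <- rep_len(seq_len(k), n)
    }
  })
  dplyr::mutate(data, fold = fold)
}

#' Area under the ROC curve
#'
#' Computed as the Mann-Whitney probability that a random positive scores
#' above a random negative, with half credit for ties:
#' `AUC = (#\{(i,j): s_i > s_j\} + 0.5 #ties) / (n_pos * n_neg)` over all
#' positive/negative pairs — identical to the trapezoidal area under the
#' ROC curve. Invariant under any strictly increasing transform of the
#' scores.
#'
#' @param scores Numeric scores (higher = more positive).
#' @param labels Binary labels (`"+1"`/`"-1"` or numeric sign).
#' @return AUC in `[0, 1]`.
#' @export
#' @examples
#' roc_auc(c(3, 2, 1, 0), c("+1", "+1", "-1", "-1"))
roc_auc <- function(scores, labels) {
  y <- label_to_y(labels)
  n_pos <- sum(y > 0)
  n_neg <- sum(y < 0)
  if (n_pos == 0 || n_neg == 0) {
    abort("AUC needs both a positive and a negative example")
  }
  r <- rank(scores)  # midranks give the half-credit tie handling
  (sum(r[y > 0]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' True-positive and false-positive rates at a probability cut-off
#'
#' A sequence is predicted positive when its probability reaches
#' `threshold` (inclusive). When a class is absent the corresponding rate
#' is undefined and returned as `NA` with a warning rather than silently 0.
#'
#' @param probs Predicted probabilities.
#' @param labels Binary labels.
#' @param threshold Cut-off, default 0.5.
#' @return Tibble with `tp_rate`, `fp_rate`, `n_pos`, `n_neg`.
#' @export
tp_fp_rates <- function(probs, labels, threshold = 0.5) {
  y <- label_to_y(labels)
  pred_pos <- probs >= threshold
  n_pos <- sum(y > 0)
  n_neg <- sum(y < 0)
  if (n_pos == 0 || n_neg == 0) {
    warn("one class is absent; the corresponding rate is NA")
  }
  tibble::tibble(
    tp_rate = if (n_pos == 0) NA_real_ else sum(pred_pos & y > 0) / n_pos,
    fp_rate = if (n_neg == 0) NA_real_ else sum(pred_pos & y < 0) / n_neg,
    n_pos = n_pos, n_neg = n_neg)
}

#' k-fold cross-validation of the binary classifier
#'
#' For each fold, trains on the other `k - 1` folds and scores the held-out
#' fold. Reports per-fold AUC and TP/FP rates plus pooled metrics over the
#' concatenated held-out scores. The fold assignment and every held-out
#' score are kept on the returned object so the same folds can be reused by
#' another method and the metrics recomputed independently.
#'
#' @inheritParams kfold_split
#' @param config An [slr_config()].
#' @param threshold Probability cut-off for the rates.
#' @return An object of class `"slr_cv"` with elements `per_fold` (tibble),
#'   `pooled` (one-row tibble), `scores` (per-sequence held-out scores) and
#'   `folds`. `tidy()` returns `per_fold`, `glance()` returns `pooled`, and
#'   `autoplot()` draws the pooled ROC curve.
#' @export
cross_validate <- function(data, config = slr_config(), k = 10, seed = 1,
                           stratify = TRUE, threshold = 0.5) {
  folded <- kfold_split(data, k = k, seed = seed, stratify = stratify)
  scores <- purrr::map_dfr(seq_len(k), function(f) {
    train <- dplyr::filter(folded, .data$fold != f)
    test <- dplyr::filter(folded, .data$fold == f)
    fit <- slr_fit(train, config = config)
    tibble::tibble(id = test$id, fold = f, label = test$label,
                   score = decision_score(test, fit),
                   prob = class_probability(test, fit))
  })
  # a fold can lack one class entirely (e.g. leave-one-out): its AUC and the
  # corresponding rate are undefined and reported as NA
  per_fold <- scores |>
    dplyr::group_by(fold = .data$fold) |>
    dplyr::group_modify(function(.x, ...) {
      y <- label_to_y(.x$label)
      auc <- if (any(y > 0) && any(y < 0)) roc_auc(.x$score, .x$label)
             else NA_real_
      dplyr::bind_cols(tibble::tibble(auc = auc),
                       suppressWarnings(tp_fp_rates(.x$prob, .x$label,
                                                    threshold)))
    }) |>
    dplyr::ungroup()
  pooled <- dplyr::bind_cols(
    tibble::tibble(auc = roc_auc(scores$score, scores$label)),
    tp_fp_rates(scores$prob, scores$label, threshold))
  structure(list(per_fold = per_fold, pooled = pooled, scores = scores,
                 folds = folded[, c("id", "fold")], k = k, seed = seed,
                 threshold = threshold),
            class = "slr_cv")
}

#' @export
print.slr_cv <- function(x, ...) {
  cat(x$k, "-fold cross-validation (seed ", x$seed, ")\n", sep = "")
  cat("pooled: AUC ", format(x$pooled$auc, digits = 4),
      ", TP rate ", format(x$pooled$tp_rate, digits = 4),
      ", FP rate ", format(x$pooled$fp_rate, digits = 4), "\n", sep = "")
  invisible(x)
}

#' @export
tidy.slr_cv <- function(x, ...) x$per_fold

#' @export
glance.slr_cv <- function(x, ...) x$pooled
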