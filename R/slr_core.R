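#' Occurrence indicator of a subsequence
#'
#' The model's features: `occurs()` is 1 when `subseq` is a contiguous
#' substring of a sequence (anywhere, any number of times) and 0 otherwise.
#' Occurrence is binary by design — the decision function uses indicator
#' features, not counts.
#'
#' @param subseq Non-empty string.
#' @param data Sequence tibble or character vector.
#' @return Integer vector of 0/1, one per sequence.
#' @export
#' @examples
#' occurs("KTG", c("MDKTGTL", "MDKGTTL"))
occurs <- function(subseq, data) {
  stopifnot(is.character(subseq), length(subseq) == 1, nzchar(subseq))
  cpp_occurs(subseq, pull_seqs(data))
}

#' Decision scores and class probabilities
#'
#' `decision_score()` evaluates the linear decision function
#' `f(x) = bias + sum_j w_j I(s_j in x)`, summing in predictor order;
#' `class_probability()` maps it through the logistic function
#' `sigma(f) = 1 / (1 + exp(-f))`, the probability that the sequence
#' belongs to the positive class.
#'
#' @inheritParams occurs
#' @param model An `slr_model`.
#' @return Numeric vector, one value per sequence.
#' @export
decision_score <- function(data, model) {
  stopifnot(inherits(model, "slr_model"))
  cpp_decision_scores(model$predictors$subseq, model$predictors$weight,
                      model$bias, pull_seqs(data))
}

#' @rdname decision_score
#' @export
class_probability <- function(data, model) {
  plogis(decision_score(data, model))
}

#' Training log-likelihood
#'
#' `L = sum_i log sigma(y_i f(x_i))`, computed with a numerically stable
#' log-sigmoid (no overflow however large the scores get). Always `<= 0`.
#'
#' @param data Sequence tibble with a binary `label` column (`"+1"`/`"-1"`).
#' @param model An `slr_model`.
#' @return A single number.
#' @export
log_likelihood <- function(data, model) {
  y <- label_to_y(data$label)
  cpp_log_likelihood(decision_score(data, model), y)
}

#' Coordinate gradient and its anti-monotone search bound
#'
#' `coordinate_gradient()` is the partial derivative of the training
#' log-likelihood with respect to the weight of `subseq`, evaluated at the
#' current scores: `sum_i y_i I(subseq in x_i) sigma(-y_i f(x_i))`.
#'
#' `gradient_bound()` returns
#' `mu(s) = max(sum_{i in D+(s)} sigma(-f_i), sum_{i in D-(s)} sigma(f_i))`
#' where `D+`/`D-` are the positive/negative sequences containing `s`.
#' Because any superstring of `s` occurs in a subset of those sequences,
#' `|coordinate_gradient(t)| <= mu(s)` for every extension `t` of `s` —
#' the pruning rule that makes the unrestricted-length search feasible.
#'
#' @inheritParams log_likelihood
#' @param subseq Candidate predictor string.
#' @param scores Current decision scores `f(x_i)`, one per sequence (e.g.
#'   from [decision_score()]).
#' @return A single number (`gradient_bound` is always `>= 0`).
#' @export
coordinate_gradient <- function(data, subseq, scores) {
  y <- label_to_y(data$label)
  seqs <- pull_seqs(data)
  stopifnot(length(scores) == length(seqs))
  cpp_coordinate_gradient(subseq, seqs, y, as.numeric(scores))
}

#' @rdname coordinate_gradient
#' @export
gradient_bound <- function(data, subseq, scores) {
  y <- label_to_y(data$label)
  seqs <- pull_seqs(data)
  stopifnot(length(scores) == length(seqs))
  cpp_gradient_bound(subseq, seqs, y, as.numeric(scores))
}

#' Find the best predictor by branch-and-bound substring search
#'
#' Explores the lattice of corpus substrings by length-increasing
#' right-extension from single characters, pruning every node (and all its
#' extensions) whose [gradient_bound()] cannot beat the best absolute
#' gradient seen so far. Only substrings with document support at least
#' `min_support` and length within `[min_len, max_len]` are eligible. The
#' result is fully deterministic: among equal gradients the shortest, then
#' lexicographically smallest substring wins.
#'
#' @inheritParams coordinate_gradient
#' @param config An [slr_config()].
#' @return List with `subseq`, `gradient` and `support`, or `NULL` when no
#'   candidate meets `min_support`.
#' @export
best_predictor_search <- function(data, scores, config = slr_config()) {
  y <- label_to_y(data$label)
  seqs <- pull_seqs(data)
  stopifnot(length(scores) == length(seqs))
  r <- cpp_best_predictor(seqs, y, as.numeric(scores), config$min_support,
                          config$min_len, max_len_int(config))
  if (!r$found) return(NULL)
  r[c("subseq", "gradient", "support")]
}

#' One-dimensional line search along a predictor coordinate
#'
#' Maximizes the restriction of the training log-likelihood to the weight
#' of `subseq`. The restriction is concave, so the maximizer is bracketed
#' by expanding steps and located by bisection on the sign of the 1-D
#' derivative, to within `config$line_search_tol`. The resulting
#' log-likelihood is never below the log-likelihood at `current_weight`.
#' A perfectly separating predictor has no finite maximizer; its weight is
#' clamped at `config$w_max` and the `separation` flag raised.
#'
#' @inheritParams best_predictor_search
#' @param subseq Predictor string; must occur in at least one sequence.
#' @param current_weight Present weight of `subseq` in the model (0 if new).
#' @return List with `weight` (the new weight) and `separation` (logical).
#' @export
line_search <- function(data, scores, subseq, current_weight = 0,
                        config = slr_config()) {
  y <- label_to_y(data$label)
  seqs <- pull_seqs(data)
  stopifnot(length(scores) == length(seqs))
  cpp_line_search(seqs, y, as.numeric(scores), subseq, current_weight,
                  config$line_search_tol, config$w_max, config$l2)
}

#' Fit a binary structured logistic regression classifier
#'
#' Iterates \{search the highest-gradient substring, line-search its weight,
#' update the cached scores\} until the largest absolute gradient falls
#' below `grad_tol`, the relative log-likelihood gain falls below
#' `loglik_rel_tol`, or `max_iters` is reached. The training log-likelihood
#' is non-decreasing across iterations. Re-selecting an already chosen
#' subsequence updates its weight in place, so the model stays compact.
#' Fitting is deterministic: identical data and configuration give an
#' identical model.
#'
#' @param data Sequence tibble with `seq` and binary `label` (`"+1"`/`"-1"`)
#'   columns; both classes must be present.
#' @param config An [slr_config()].
#' @param class_label Optional class name stored in the model (used by the
#'   one-vs-all cascade).
#' @return An `slr_model`; its `trace` element records iteration, chosen
#'   predictor, gradient, weight and log-likelihood for each step.
#' @export
#' @examples
#' d <- tibble::tibble(
#'   id = c("p1", "p2", "n1", "n2"),
#'   seq = c("MADKTGTLLA", "GGDKTGTWYC", "MAGLLWYCAA", "GGPQRSTWYC"),
#'   label = c("+1", "+1", "-1", "-1"))
#' fit <- slr_fit(d)
#' class_probability(d, fit)
slr_fit <- function(data, config = slr_config(), class_label = NA_character_) {
  y <- check_binary_data(data)
  seqs <- pull_seqs(data)
  res <- cpp_train(seqs, y, config$max_iters, config$grad_tol,
                   config$loglik_rel_tol, config$min_support, config$min_len,
                   max_len_int(config), config$line_search_tol, config$w_max,
                   config$refresh_every, config$l2, config$fit_bias)
  new_slr_model(
    predictors = tibble::tibble(subseq = res$predictors, weight = res$weights),
    bias = res$bias, class_label = class_label, config = config,
    trace = tibble::as_tibble(res$trace),
    converged = !identical(res$stop_reason, "max_iters"),
    separation = res$separation, loglik = res$loglik, n_train = length(seqs))
}
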