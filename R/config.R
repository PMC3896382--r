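#' Training configuration
#'
#' Bundles the tunable parameters of the coordinate-ascent trainer. The
#' defaults are this package's own; they are deliberately conservative and
#' every one of them is recorded in the model-file header so a persisted
#' model documents how it was fit.
#'
#' @param max_iters Maximum number of coordinate steps (default 1000). Each
#'   step selects one predictor and optimizes its weight.
#' @param grad_tol Stop when the largest absolute likelihood gradient over
#'   all candidate substrings falls below this value (default `1e-4`).
#' @param loglik_rel_tol Stop when the relative log-likelihood gain of a
#'   step falls below this value (default `1e-9`).
#' @param min_support Minimum number of training sequences a candidate
#'   predictor must occur in (default 1). Raising it shrinks the search
#'   space considerably on large corpora.
#' @param min_len,max_len Length bounds for predictors (defaults 1 and
#'   `Inf`, i.e. unrestricted; candidates are corpus substrings, so the data
#'   bounds the length in practice).
#' @param line_search_tol Bracket width at which the 1-D bisection stops
#'   (default `1e-10`).
#' @param w_max Weight clamp applied when a predictor perfectly separates
#'   the classes, where the unregularized likelihood has no finite maximizer
#'   (default 50; the logistic function saturates far below that).
#' @param refresh_every Recompute cached decision scores from scratch every
#'   this many steps to guard against incremental drift (default 25).
#' @param l2 Optional ridge penalty `l2/2 * sum(w^2)` subtracted from the
#'   log-likelihood (default 0 = off, the canonical unpenalized fit). A
#'   small positive value keeps weights finite under separation and stops
#'   the trainer from memorizing individual training sequences — useful for
#'   one-vs-all models with few positives. With a penalty, fresh candidates
#'   are still selected by data gradient (a zero-weight coordinate has no
#'   penalty gradient) while already-selected coordinates compete with
#'   their penalized gradients; any penalty used is recorded in the model
#'   header via the configuration digest.
#' @param fit_bias Optimize the intercept as an always-on, never-penalized
#'   coordinate (default `FALSE`: the canonical decision function has no
#'   intercept). With heavily imbalanced one-vs-all training sets the
#'   fitted bias absorbs the class prior, which otherwise gets spread over
#'   a collinear set of near-ubiquitous short predictors.
#' @param seed Integer seed recorded for callers that shuffle or simulate;
#'   the trainer itself is deterministic and never draws random numbers.
#'
#' @return A list of class `"slr_config"`.
#' @export
#' @examples
#' slr_config(min_len = 5, max_iters = 200)
slr_config <- function(max_iters = 1000, grad_tol = 1e-4, loglik_rel_tol = 1e-9,
                       min_support = 1, min_len = 1, max_len = Inf,
                       line_search_tol = 1e-10, w_max = 50, refresh_every = 25,
                       l2 = 0, fit_bias = FALSE, seed = 1L) {
  stopifnot(max_iters >= 0, grad_tol > 0, loglik_rel_tol > 0,
            min_support >= 1, min_len >= 1, max_len >= min_len,
            line_search_tol > 0, w_max > 0, l2 >= 0)
  structure(list(max_iters = as.integer(max_iters), grad_tol = grad_tol,
                 loglik_rel_tol = loglik_rel_tol,
                 min_support = as.integer(min_support),
                 min_len = as.integer(min_len), max_len = max_len,
                 line_search_tol = line_search_tol, w_max = w_max,
                 refresh_every = as.integer(refresh_every), l2 = l2,
                 fit_bias = isTRUE(fit_bias), seed = as.integer(seed)),
            class = "slr_config")
}

# length bound as understood by the C++ search (0 = unbounded)
max_len_int <- function(config) {
  if (is.infinite(config$max_len)) 0L else as.integer(config$max_len)
}

config_digest <- function(config) {
  vals <- vapply(config, function(v) format(v, digits = 17), character(1))
  paste(paste0(names(config), "=", vals), collapse = ";")
}
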