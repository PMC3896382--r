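#' Construct a structured logistic regression model object
#'
#' Rarely called directly; [slr_fit()] and [read_model()] return these. A
#' model is an ordered set of subsequence predictors with weights. Order is
#' the selection order and is preserved everywhere (including score
#' summation) so that serialized models reproduce decision scores
#' bit-exactly.
#'
#' @param predictors Tibble with columns `subseq` (non-empty strings over
#'   [amino_alphabet()]) and `weight` (finite reals); no duplicate `subseq`.
#' @param bias Intercept, default 0. The canonical decision function has no
#'   intercept; the slot exists for completeness and is persisted.
#' @param class_label Optional class name this binary model discriminates
#'   (the positive class of a one-vs-all split).
#' @param config The [slr_config()] used for training, if any.
#' @param trace Per-iteration training trace.
#' @param converged,separation,loglik,n_train Training diagnostics.
#'
#' @return An object of class `"slr_model"`.
#' @export
new_slr_model <- function(predictors = tibble::tibble(subseq = character(),
                                                      weight = numeric()),
                          bias = 0, class_label = NA_character_, config = NULL,
                          trace = NULL, converged = NA, separation = FALSE,
                          loglik = NA_real_, n_train = NA_integer_) {
  predictors <- tibble::as_tibble(predictors)
  stopifnot(all(c("subseq", "weight") %in% names(predictors)))
  if (nrow(predictors) > 0) {
    if (anyDuplicated(predictors$subseq)) abort("duplicate predictor subsequences")
    if (any(!nzchar(predictors$subseq))) abort("empty predictor subsequence")
    if (any(!is.finite(predictors$weight))) abort("non-finite predictor weight")
  }
  structure(list(predictors = predictors, bias = bias, class_label = class_label,
                 config = config, trace = trace, converged = converged,
                 separation = separation, loglik = loglik,
                 n_train = n_train),
            class = "slr_model")
}

#' @export
print.slr_model <- function(x, ...) {
  k <- nrow(x$predictors)
  cat("Structured logistic regression model")
  if (!is.na(x$class_label)) cat(" [class ", x$class_label, "]", sep = "")
  cat("\n", k, " predictor(s), bias ", format(x$bias), sep = "")
  if (!is.na(x$loglik)) cat(", training log-likelihood ", format(x$loglik), sep = "")
  cat("\n")
  if (k > 0) {
    shown <- dplyr::arrange(x$predictors, dplyr::desc(abs(.data$weight)))
    print(utils::head(shown, 10))
    if (k > 10) cat("# ... with", k - 10, "more predictors\n")
  }
  invisible(x)
}

#' @rdname new_slr_model
#' @param x An `slr_model`.
#' @param ... Unused.
#' @export
tidy.slr_model <- function(x, ...) {
  dplyr::mutate(x$predictors, rank = dplyr::row_number(), .before = 1)
}

#' @rdname new_slr_model
#' @export
glance.slr_model <- function(x, ...) {
  tibble::tibble(k = nrow(x$predictors), bias = x$bias, loglik = x$loglik,
                 iterations = if (is.null(x$trace)) NA_integer_ else nrow(x$trace),
                 converged = x$converged, separation = x$separation,
                 n_train = x$n_train)
}

#' Predict from a structured logistic regression model
#'
#' @param object An `slr_model`.
#' @param data Sequence tibble (or character vector of residue strings).
#' @param type `"prob"` for class-membership probabilities, `"score"` for
#'   raw decision scores, `"class"` for `"+1"`/`"-1"` at `threshold`.
#' @param threshold Probability cut-off for `type = "class"` (default 0.5,
#'   inclusive).
#' @param ... Unused.
#' @return Numeric (or character, for `"class"`) vector, one value per
#'   sequence.
#' @export
predict.slr_model <- function(object, data, type = c("prob", "score", "class"),
                              threshold = 0.5, ...) {
  type <- match.arg(type)
  f <- decision_score(data, object)
  switch(type,
         score = f,
         prob = plogis(f),
         class = ifelse(plogis(f) >= threshold, "+1", "-1"))
}

# ---------------------------------------------------------------------------
# Model persistence
# ---------------------------------------------------------------------------

#' Write / read a model file
#'
#' Models are persisted as line-oriented text: header lines of the form
#' `# key=value` (class label, bias, training-configuration digest),
#' followed by one `predictor<TAB>weight` line per predictor in selection
#' order. Weights are serialized with 17 significant digits, so the round
#' trip is exact: a re-read model reproduces decision scores bit-for-bit.
#'
#' @param model An `slr_model`.
#' @param path File path.
#' @return `write_model` returns `path` invisibly; `read_model` returns an
#'   `slr_model`.
#' @export
#' @examples
#' m <- new_slr_model(tibble::tibble(subseq = "DKTGT", weight = 2.5))
#' f <- tempfile(fileext = ".tsv")
#' write_model(m, f)
#' read_model(f)
write_model <- function(model, path) {
  stopifnot(inherits(model, "slr_model"))
  header <- c("# seqslr_model=1",
              paste0("# class=", ifelse(is.na(model$class_label), "",
                                        model$class_label)),
              paste0("# bias=", sprintf("%.17g", model$bias)),
              paste0("# config=", if (is.null(model$config)) ""
                     else config_digest(model$config)))
  body <- sprintf("%s\t%.17g", model$predictors$subseq, model$predictors$weight)
  write_lines_atomic(c(header, body), path)
  invisible(path)
}

#' @rdname write_model
#' @export
read_model <- function(path) {
  lines <- readr::read_lines(path, progress = FALSE)
  is_header <- stringr::str_starts(lines, "#")
  headers <- lines[is_header]
  kv <- stringr::str_match(headers, "^#\\s*([^=]+)=(.*)$")
  keys <- kv[, 2]
  vals <- kv[, 3]
  get_key <- function(k, default = "") {
    i <- match(k, keys)
    if (is.na(i)) default else vals[i]
  }
  class_label <- get_key("class")
  if (!nzchar(class_label)) class_label <- NA_character_
  bias <- suppressWarnings(as.numeric(get_key("bias", "0")))
  if (is.na(bias)) abort(paste0("malformed bias header in ", path))
  body_idx <- which(!is_header & nzchar(lines))
  parts <- stringr::str_split(lines[body_idx], "\t")
  n_fields <- lengths(parts)
  if (any(n_fields != 2)) {
    abort(paste0("malformed model line ", body_idx[which(n_fields != 2)[1]],
                 " in ", path, " (expected predictor<TAB>weight)"))
  }
  subseq <- vapply(parts, `[[`, character(1), 1)
  weight <- suppressWarnings(as.numeric(vapply(parts, `[[`, character(1), 2)))
  if (anyNA(weight)) {
    abort(paste0("non-numeric weight at model line ",
                 body_idx[which(is.na(weight))[1]], " in ", path))
  }
  if (anyDuplicated(subseq)) {
    abort(paste0("duplicate predictor in model file ", path))
  }
  new_slr_model(tibble::tibble(subseq = subseq, weight = weight), bias = bias,
                class_label = class_label)
}
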