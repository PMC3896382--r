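#' Build one-vs-all binary training sets
#'
#' For each class `c` in `classes`, relabels the data `"+1"` where the
#' original label equals `c` and `"-1"` elsewhere, preserving sequence
#' order. Every sequence must carry a class label.
#'
#' @param data Sequence tibble with a `label` column of class names.
#' @param classes Ordered class list; defaults to the classes present, in
#'   [ptype_classes()] order when they all belong to it, alphabetical
#'   otherwise. The order is meaningful: it is the argmax tie-break.
#' @return Named list of binary sequence tibbles, one per class.
#' @export
build_one_vs_all <- function(data, classes = NULL) {
  classes <- resolve_classes(data$label, classes)
  unlabeled <- !(data$label %in% classes)
  if (any(unlabeled)) {
    abort(paste0("sequence(s) without a class label: ",
                 paste(utils::head(data$id[unlabeled], 5), collapse = ", ")))
  }
  out <- lapply(classes, function(cl) {
    dplyr::mutate(data, label = ifelse(.data$label == cl, "+1", "-1"))
  })
  setNames(out, classes)
}

resolve_classes <- function(labels, classes) {
  if (!is.null(classes)) return(classes)
  present <- unique(labels[labels != "unlabeled"])
  if (all(present %in% ptype_classes())) {
    intersect(ptype_classes(), present)
  } else {
    sort(present)
  }
}

#' Fit the one-vs-all multiclass cascade
#'
#' Trains one binary structured logistic regression model per class on the
#' one-vs-all relabeling of the data.
#'
#' @inheritParams build_one_vs_all
#' @param config An [slr_config()] shared by all class models.
#' @return An object of class `"slr_multiclass"`: the ordered class list
#'   plus one `slr_model` per class.
#' @export
slr_fit_multiclass <- function(data, classes = NULL, config = slr_config()) {
  classes <- resolve_classes(data$label, classes)
  sets <- build_one_vs_all(data, classes)
  models <- lapply(classes, function(cl) {
    slr_fit(sets[[cl]], config = config, class_label = cl)
  })
  structure(list(classes = classes, models = setNames(models, classes),
                 config = config),
            class = "slr_multiclass")
}

#' @export
print.slr_multiclass <- function(x, ...) {
  cat("One-vs-all SLR cascade over", length(x$classes), "classes:",
      paste(x$classes, collapse = ", "), "\n")
  k <- vapply(x$models, function(m) nrow(m$predictors), integer(1))
  cat("predictors per class:", paste(k, collapse = ", "), "\n")
  invisible(x)
}

#' @export
tidy.slr_multiclass <- function(x, ...) {
  purrr::map_dfr(x$models, function(m) {
    dplyr::mutate(tidy(m), class = m$class_label, .before = 1)
  })
}

#' @export
glance.slr_multiclass <- function(x, ...) {
  purrr::map_dfr(x$models, function(m) {
    dplyr::mutate(glance(m), class = m$class_label, .before = 1)
  })
}

#' Screen sequences with a binary classifier
#'
#' The identification step: keep the sequences whose class-membership
#' probability reaches `threshold` (default 0.5, the probability midpoint,
#' inclusive — an empty model scores everything exactly 0.5 and passes
#' everything).
#'
#' @param data Sequence tibble.
#' @param model A trained `slr_model`.
#' @param threshold Probability cut-off in `[0, 1]`.
#' @return The qualifying rows of `data`, in input order, with a `prob`
#'   column appended.
#' @export
screen_sequences <- function(data, model, threshold = 0.5) {
  p <- class_probability(data, model)
  dplyr::filter(dplyr::mutate(data, prob = p), .data$prob >= threshold)
}

#' Classify sequences with the multiclass cascade
#'
#' Every sequence is scored by all class models and all probabilities are
#' stored. A sequence is assigned to the maximum-probability class (ties
#' broken by class-list order, first wins); if every probability is below
#' 0.5 the sequence is rejected into class `"0"` with an assigned score of
#' 0.5, preserving in the stored probabilities how far it was from
#' inclusion in any class.
#'
#' @param data Sequence tibble.
#' @param mm An `slr_multiclass` cascade.
#' @return Tibble with columns `id`, `assigned`, `assigned_score`, then one
#'   probability column `p_<class>` per class in class-list order.
#' @export
classify_sequences <- function(data, mm) {
  stopifnot(inherits(mm, "slr_multiclass"))
  if (nrow(data) == 0) {
    out <- tibble::tibble(id = character(), assigned = character(),
                          assigned_score = numeric())
    for (cl in mm$classes) out[[paste0("p_", cl)]] <- numeric()
    return(out)
  }
  probs <- vapply(mm$classes, function(cl) class_probability(data, mm$models[[cl]]),
                  numeric(nrow(data)))
  probs <- matrix(probs, nrow = nrow(data),
                  dimnames = list(NULL, mm$classes))
  best <- apply(probs, 1, which.max)  # first maximum = class-list tie-break
  best_p <- probs[cbind(seq_len(nrow(probs)), best)]
  rejected <- apply(probs < 0.5, 1, all)
  out <- tibble::tibble(
    id = pull_ids(data),
    assigned = ifelse(rejected, "0", mm$classes[best]),
    assigned_score = ifelse(rejected, 0.5, best_p))
  pcols <- tibble::as_tibble(probs, .name_repair = "minimal")
  names(pcols) <- paste0("p_", mm$classes)
  dplyr::bind_cols(out, pcols)
}

#' Iterative self-training until the test labeling is stable
#'
#' Round 0 trains the cascade on `seed_train` and labels all of `test`.
#' Each later round augments the training set with the test sequences under
#' their currently assigned class (class-0 rejections carry no class label
#' and are excluded), retrains, and relabels the full test set. The seed
#' labels are never overwritten. Iteration stops at a fixed point (the full
#' test label vector unchanged between consecutive rounds — which makes the
#' final labeling idempotent by construction), after `max_rounds`
#' retraining rounds (flagged not converged), or when a label vector
#' repeats a non-adjacent earlier round (flagged as a cycle).
#'
#' @param seed_train Fully class-labeled sequence tibble.
#' @param test Sequence tibble to label (labels ignored).
#' @param classes Ordered class list (see [build_one_vs_all()]).
#' @param config An [slr_config()].
#' @param max_rounds Maximum retraining rounds beyond round 0; `0` returns
#'   the round-0 labeling with the convergence check skipped.
#' @return List with `model` (final cascade), `records` (final
#'   classification tibble), `rounds_used`, `converged` and `cycle`.
#' @export
retrain_until_stable <- function(seed_train, test, classes = NULL,
                                 config = slr_config(), max_rounds = 10) {
  classes <- resolve_classes(seed_train$label, classes)
  mm <- slr_fit_multiclass(seed_train, classes, config)
  if (nrow(test) == 0) {
    return(list(model = mm, records = classify_sequences(test[0, ], mm),
                rounds_used = 0L, converged = TRUE, cycle = FALSE))
  }
  records <- classify_sequences(test, mm)
  history <- list(records$assigned)
  converged <- FALSE
  cycle <- FALSE
  rounds <- 0L
  if (max_rounds >= 1) {
    for (r in seq_len(max_rounds)) {
      keep <- records$assigned != "0"
      aug <- dplyr::bind_rows(
        seed_train,
        dplyr::mutate(test[keep, ], label = records$assigned[keep]))
      mm <- slr_fit_multiclass(aug, classes, config)
      records <- classify_sequences(test, mm)
      rounds <- r
      if (identical(records$assigned, history[[length(history)]])) {
        converged <- TRUE
        break
      }
      seen <- vapply(utils::head(history, -1), identical, logical(1),
                     y = records$assigned)
      if (any(seen)) {
        cycle <- TRUE
        break
      }
      history[[length(history) + 1]] <- records$assigned
    }
    if (!converged && !cycle) {
      warn("retraining reached max_rounds without a stable labeling")
    }
  } else {
    converged <- NA
  }
  list(model = mm, records = records, rounds_used = rounds,
       converged = converged, cycle = cycle)
}

# persistence of a cascade as a directory of model files (CLI)
write_multiclass <- function(mm, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_lines_atomic(mm$classes, file.path(dir, "classes.txt"))
  for (cl in mm$classes) {
    write_model(mm$models[[cl]], file.path(dir, paste0("model_", cl, ".tsv")))
  }
  invisible(dir)
}

read_multiclass <- function(dir) {
  cfile <- file.path(dir, "classes.txt")
  if (!file.exists(cfile)) abort(paste0("not a cascade directory: ", dir))
  classes <- readr::read_lines(cfile, progress = FALSE)
  models <- lapply(classes, function(cl) {
    read_model(file.path(dir, paste0("model_", cl, ".tsv")))
  })
  structure(list(classes = classes, models = setNames(models, classes),
                 config = NULL),
            class = "slr_multiclass")
}
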