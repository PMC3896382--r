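# a hand-built cascade whose class probabilities are known exactly
fixed_cascade <- function(classes, weights_by_class) {
  models <- lapply(classes, function(cl) {
    w <- weights_by_class[[cl]]
    new_slr_model(tibble::tibble(subseq = names(w), weight = unname(w)),
                  class_label = cl)
  })
  structure(list(classes = classes, models = setNames(models, classes),
                 config = NULL), class = "slr_multiclass")
}

test_that("build_one_vs_all relabels each class against the rest", {
  d <- tibble::tibble(id = c("x", "y", "z"), seq = c("AAA", "CCC", "GGG"),
                      label = c("a", "b", "c"))
  sets <- build_one_vs_all(d, classes = c("a", "b", "c"))
  expect_named(sets, c("a", "b", "c"))
  for (cl in names(sets)) {
    expect_equal(sum(sets[[cl]]$label == "+1"), 1)
    expect_equal(sum(sets[[cl]]$label == "-1"), 2)
    expect_equal(sets[[cl]]$id[sets[[cl]]$label == "+1"], d$id[d$label == cl])
    expect_equal(sets[[cl]]$id, d$id)  # order preserved
  }
  # positive counts across the datasets partition n
  npos <- vapply(sets, function(s) sum(s$label == "+1"), integer(1))
  expect_equal(sum(npos), nrow(d))
  d$label[2] <- "unlabeled"
  expect_error(build_one_vs_all(d, classes = c("a", "b", "c")), "without a class")
})

test_that("classify_sequences applies argmax, rejection and tie-break rules", {
  # every model carries a baseline penalty on the ubiquitous "A" so that
  # sequences without the class predictor sit strictly below 0.5
  mm <- fixed_cascade(c("IB", "IIA", "IV"), list(
    IB = c(A = -1, DK = 2), IIA = c(A = -1, WW = 3), IV = c(A = -1, DK = 2)))
  d <- tibble::tibble(id = c("hit_iia", "tie_ib_iv", "reject"),
                      seq = c("AWWA", "ADKA", "AAAA"),
                      label = "unlabeled")
  rec <- classify_sequences(d, mm)
  expect_equal(names(rec), c("id", "assigned", "assigned_score",
                             "p_IB", "p_IIA", "p_IV"))
  expect_equal(rec$assigned, c("IIA", "IB", "0"))  # tie goes to earlier class
  expect_equal(rec$assigned_score[1], plogis(2), tolerance = 1e-12)
  expect_equal(rec$assigned_score[3], 0.5)  # class-0 assigned score rule
  # the class-0 rule holds exactly on every record
  pm <- as.matrix(rec[, c("p_IB", "p_IIA", "p_IV")])
  expect_equal(rec$assigned == "0", apply(pm < 0.5, 1, all))
  expect_equal(rec$assigned_score[rec$assigned != "0"],
               apply(pm, 1, max)[rec$assigned != "0"])
})

test_that("screen_sequences keeps order and respects the inclusive cut-off", {
  d <- tibble::tibble(id = c("a", "b", "c"), seq = c("XDKX", "XXXX", "YDKY"),
                      label = "unlabeled")
  # empty model: everything sits exactly at 0.5 and passes (inclusive)
  expect_equal(screen_sequences(d, new_slr_model())$id, d$id)
  # threshold 1 can never be reached by a logistic probability
  m <- new_slr_model(tibble::tibble(subseq = c("X", "DK"), weight = c(-5, 30)))
  expect_equal(nrow(screen_sequences(d, m, threshold = 1)), 0)
  expect_equal(screen_sequences(d, m)$id, c("a", "c"))
})

test_that("retraining stops at a fixed point and the guard rails work", {
  spec <- synthetic_spec(n_classes = 3,
                         motifs = list(a = "WDKTGTLW", b = "CYHENMRA",
                                       c = "PGFDAYKT"),
                         motif_presence = 1, fragment_fraction = 0,
                         substitution_noise = 0, length_range = c(80, 140),
                         n_per_class = 12, n_negatives = 0, seed = 21)
  g <- generate_multiclass(spec)
  seqs <- g$sequences
  seed_train <- seqs[c(1:8, 13:20, 25:32), ]
  test <- dplyr::mutate(seqs[c(9:12, 21:24, 33:36), ], label = "unlabeled")
  cfg <- slr_config(max_iters = 50)
  res <- retrain_until_stable(seed_train, test, classes = c("a", "b", "c"),
                              config = cfg, max_rounds = 10)
  expect_true(res$converged)
  expect_false(res$cycle)
  expect_lte(res$rounds_used, 5)
  # the planted classes are recovered
  expect_equal(res$records$assigned, g$manifest$true_class[c(9:12, 21:24, 33:36)])
  # natural termination implies idempotence: one more round changes nothing
  aug <- dplyr::bind_rows(seed_train,
                          dplyr::mutate(test, label = res$records$assigned))
  mm2 <- slr_fit_multiclass(aug, c("a", "b", "c"), cfg)
  expect_equal(classify_sequences(test, mm2)$assigned, res$records$assigned)

  # max_rounds = 0 returns round-0 labels with the check skipped
  r0 <- retrain_until_stable(seed_train, test, classes = c("a", "b", "c"),
                             config = cfg, max_rounds = 0)
  expect_equal(r0$rounds_used, 0L)
  expect_true(is.na(r0$converged))

  # empty test set converges trivially
  re <- retrain_until_stable(seed_train, test[0, ], classes = c("a", "b", "c"),
                             config = cfg)
  expect_true(re$converged)
  expect_equal(re$rounds_used, 0L)
  expect_equal(nrow(re$records), 0)
})

test_that("cascade round-trips through a model directory", {
  d <- toy_separable()
  d$label <- rep(c("IIA", "IV"), each = 3)
  mm <- slr_fit_multiclass(d, config = slr_config(max_iters = 30))
  dir <- withr::local_tempdir()
  write_multiclass <- getFromNamespace("write_multiclass", "seqslr")
  read_multiclass <- getFromNamespace("read_multiclass", "seqslr")
  write_multiclass(mm, dir)
  back <- read_multiclass(dir)
  expect_equal(back$classes, mm$classes)
  expect_equal(classify_sequences(d, back), classify_sequences(d, mm))
})
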