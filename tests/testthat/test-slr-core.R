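test_that("occurs is a position-independent substring indicator", {
  expect_equal(occurs("KTG", c("MDKTGTL", "MDKGTTL")), c(1L, 0L))
  expect_equal(occurs("AA", "AAA"), 1L)  # overlapping occurrences count once
  expect_equal(occurs("AAAA", "AAA"), 0L)
})

test_that("decision_score sums weights of present predictors in order", {
  empty <- new_slr_model()
  expect_equal(decision_score("XABX", empty), 0)
  m1 <- new_slr_model(tibble::tibble(subseq = "AB", weight = 1.2))
  expect_equal(decision_score("XABX", m1), 1.2)
  m2 <- new_slr_model(tibble::tibble(subseq = c("AB", "BX"),
                                     weight = c(1.2, -0.5)))
  expect_equal(decision_score("XABX", m2), 0.7)
  expect_equal(decision_score("QQQQ", m2), 0)
})

test_that("class_probability is the logistic of the score and never overflows", {
  m <- new_slr_model(tibble::tibble(subseq = "AB", weight = 1.2))
  expect_equal(class_probability("QQ", m), 0.5)
  expect_equal(class_probability("AB", m), 1 / (1 + exp(-1.2)),
               tolerance = 1e-12)
  # monotone in the score
  big <- new_slr_model(tibble::tibble(subseq = "AB", weight = -1e4))
  p <- class_probability("AB", big)
  expect_gte(p, 0)
  expect_lt(p, 1e-300)
})

test_that("log_likelihood matches hand sums and stays finite at |f| = 1e4", {
  d <- tibble::tibble(id = c("a", "b"), seq = c("XABX", "XQQX"),
                      label = c("+1", "-1"))
  expect_equal(log_likelihood(d, new_slr_model()), 2 * log(0.5))
  m <- new_slr_model(tibble::tibble(subseq = "AB", weight = 0.8))
  hand <- plogis(1 * 0.8, log.p = TRUE) + plogis(-1 * 0, log.p = TRUE)
  expect_equal(log_likelihood(d, m), hand, tolerance = 1e-12)
  expect_lte(log_likelihood(d, m), 0)
  mbig <- new_slr_model(tibble::tibble(subseq = c("AB", "QQ"),
                                       weight = c(1e4, -1e4)))
  expect_true(is.finite(log_likelihood(d, mbig)))
  d$label[2] <- "unlabeled"
  expect_error(log_likelihood(d, m), "\\+1")
})

test_that("coordinate_gradient matches the closed form at zero scores", {
  d <- tibble::tibble(id = letters[1:5],
                      seq = c("AAB", "CAB", "GAB", "CCD", "CCE"),
                      label = c("+1", "+1", "+1", "-1", "-1"))
  z <- rep(0, 5)
  # "AB" occurs in 3 positives, 0 negatives
  expect_equal(coordinate_gradient(d, "AB", z), 0.5 * (3 - 0))
  # "C" occurs in 1 positive, 2 negatives
  expect_equal(coordinate_gradient(d, "C", z), 0.5 * (1 - 2))
  expect_equal(coordinate_gradient(d, "ZZZ", z), 0)
  expect_equal(gradient_bound(d, "C", z), 0.5 * max(1, 2))
  expect_equal(gradient_bound(d, "ZZZ", z), 0)
})

test_that("coordinate_gradient equals central finite differences", {
  for (seed in 1:10) {
    inst <- random_instance(seed)
    seqs <- inst$data$seq
    preds <- c(substr(seqs[1], 1, 2), substr(seqs[2], 2, 4))
    ws <- c(0.7, -0.4)
    f <- rep(0, length(seqs))
    for (j in seq_along(preds)) {
      f <- f + ws[j] * as.numeric(grepl(preds[j], seqs, fixed = TRUE))
    }
    target <- substr(seqs[1], 1, 3)
    h <- 1e-5
    fd <- (oracle_loglik(seqs, inst$y, c(preds, target), c(ws, h)) -
           oracle_loglik(seqs, inst$y, c(preds, target), c(ws, -h))) / (2 * h)
    expect_equal(coordinate_gradient(inst$data, target, f), fd,
                 tolerance = 1e-6)
  }
})

test_that("gradient_bound dominates every corpus superstring's gradient", {
  for (seed in 1:5) {
    inst <- random_instance(seed, n_range = c(4, 8), len_range = c(6, 12),
                            alpha_n = 3)
    seqs <- inst$data$seq
    subs <- all_substrings(seqs)
    for (s in subs[nchar(subs) <= 3]) {
      mu <- gradient_bound(inst$data, s, inst$scores)
      sup <- subs[grepl(s, subs, fixed = TRUE)]
      g <- vapply(sup, oracle_gradient, numeric(1), seqs = seqs,
                  y = inst$y, scores = inst$scores)
      expect_true(all(abs(g) <= mu + 1e-12))
    }
  }
})

test_that("best_predictor_search honours tie-breaks and min_support", {
  d <- tibble::tibble(id = c("a", "b"), seq = c("AAB", "CCD"),
                      label = c("+1", "-1"))
  r <- best_predictor_search(d, c(0, 0))
  expect_equal(abs(r$gradient), 0.5)
  expect_equal(r$subseq, "A")  # shortest, then lexicographically smallest
  expect_null(best_predictor_search(d, c(0, 0),
                                    slr_config(min_support = 3)))
  # length bounds restrict the candidate set
  r2 <- best_predictor_search(d, c(0, 0), slr_config(min_len = 2))
  expect_gte(nchar(r2$subseq), 2)
})

test_that("line_search finds the 1-D maximizer and flags separation", {
  d <- toy_separable()
  z <- rep(0, nrow(d))
  # predictor only in positives: no finite maximizer
  r <- line_search(d, z, "DKTGT")
  expect_gt(r$weight, 0)
  expect_true(r$separation)
  expect_equal(r$weight, slr_config()$w_max)
  # symmetric predictor: gradient zero, weight unchanged
  ds <- tibble::tibble(id = c("p", "n"), seq = c("XABX", "YABY"),
                       label = c("+1", "-1"))
  expect_equal(line_search(ds, c(0, 0), "AB", current_weight = 0.3)$weight, 0.3)
  # grid-scan oracle on a 3-sequence instance
  d3 <- tibble::tibble(id = c("a", "b", "c"), seq = c("QABQ", "RABR", "SXYS"),
                       label = c("+1", "-1", "-1"))
  grid <- seq(-10, 10, by = 1e-4)
  ll <- vapply(grid, function(w) oracle_loglik(d3$seq, c(1, -1, -1), "AB", w),
               numeric(1))
  expect_equal(line_search(d3, rep(0, 3), "AB")$weight, grid[which.max(ll)],
               tolerance = 1e-3)
  expect_error(line_search(d3, rep(0, 3), "ZZZ"), "no sequence")
})

test_that("slr_fit separates a planted-motif toy set and respects contracts", {
  d <- toy_separable()
  fit <- slr_fit(d)
  p <- class_probability(d, fit)
  expect_true(all(p[d$label == "+1"] > 0.5))
  expect_true(all(p[d$label == "-1"] < 0.5))
  # log-likelihood non-decreasing along the trace
  ll <- c(nrow(d) * log(0.5), fit$trace$loglik)
  expect_true(all(diff(ll) >= -1e-12))
  # deterministic
  expect_identical(slr_fit(d)$predictors, fit$predictors)
  # max_iters = 0: empty model, everything at probability 0.5
  f0 <- slr_fit(d, slr_config(max_iters = 0))
  expect_equal(nrow(f0$predictors), 0)
  expect_equal(class_probability(d, f0), rep(0.5, nrow(d)))
  # single-class data is an error
  expect_error(slr_fit(dplyr::mutate(d, label = "+1")), "positive and a negative")
})

test_that("re-selection updates a predictor's weight without duplicating it", {
  withr::with_seed(3, {
    d <- tibble::tibble(
      id = paste0("s", 1:40),
      seq = vapply(rep(30, 40), random_aa_string, character(1),
                   alphabet = AA20[1:6]),
      label = rep(c("+1", "-1"), 20))
  })
  fit <- slr_fit(d, slr_config(max_iters = 60))
  expect_false(anyDuplicated(fit$predictors$subseq) > 0)
  expect_lte(nrow(fit$predictors), nrow(fit$trace))
})
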