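# Independent oracles and fixture builders.  Oracles deliberately avoid the
# code paths they check: occurrence via grepl(fixed = TRUE), likelihood via
# plogis, search via exhaustive substring enumeration.

AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

random_aa_string <- function(len, alphabet = AA20) {
  paste(sample(alphabet, len, replace = TRUE), collapse = "")
}

# a small random labeled corpus over a reduced alphabet
random_instance <- function(seed, n_range = c(5, 30), len_range = c(8, 30),
                            alpha_n = 4) {
  withr::with_seed(seed, {
    n <- sample(n_range[1]:n_range[2], 1)
    alphabet <- AA20[seq_len(alpha_n)]
    seqs <- vapply(sample(len_range[1]:len_range[2], n, replace = TRUE),
                   random_aa_string, character(1), alphabet = alphabet)
    y <- sample(c(-1L, 1L), n, replace = TRUE)
    if (all(y > 0)) y[1] <- -1L
    if (all(y < 0)) y[1] <- 1L
    scores <- stats::rnorm(n)
    list(data = tibble::tibble(id = paste0("s", seq_len(n)), seq = seqs,
                               label = ifelse(y > 0, "+1", "-1")),
         y = y, scores = scores)
  })
}

# every distinct substring of the corpus up to max_len
all_substrings <- function(seqs, max_len = Inf) {
  unique(unlist(lapply(seqs, function(s) {
    n <- nchar(s)
    unlist(lapply(seq_len(min(max_len, n)), function(l) {
      substring(s, seq_len(n - l + 1), seq(l, n))
    }))
  })))
}

oracle_gradient <- function(subseq, seqs, y, scores) {
  occ <- grepl(subseq, seqs, fixed = TRUE)
  sum(y[occ] * plogis(-y[occ] * scores[occ]))
}

oracle_bound <- function(subseq, seqs, y, scores) {
  occ <- grepl(subseq, seqs, fixed = TRUE)
  max(sum(plogis(-scores[occ & y > 0])), sum(plogis(scores[occ & y < 0])))
}

# brute-force maximum |gradient| over all corpus substrings
oracle_best <- function(seqs, y, scores, min_support = 1, min_len = 1,
                        max_len = Inf) {
  subs <- all_substrings(seqs, max_len)
  subs <- subs[nchar(subs) >= min_len]
  subs <- subs[order(nchar(subs), subs)]
  best <- NULL
  best_abs <- -1
  for (s in subs) {
    occ <- grepl(s, seqs, fixed = TRUE)
    if (sum(occ) < min_support) next
    g <- sum(y[occ] * plogis(-y[occ] * scores[occ]))
    if (abs(g) > best_abs) {
      best_abs <- abs(g)
      best <- list(subseq = s, gradient = g)
    }
  }
  best
}

# log-likelihood evaluated independently of the package
oracle_loglik <- function(seqs, y, preds, ws) {
  f <- rep(0, length(seqs))
  for (j in seq_along(preds)) {
    f <- f + ws[j] * as.numeric(grepl(preds[j], seqs, fixed = TRUE))
  }
  sum(plogis(y * f, log.p = TRUE))
}

# a tiny linearly separable binary corpus built around a planted motif
toy_separable <- function() {
  tibble::tibble(
    id = c("p1", "p2", "p3", "n1", "n2", "n3"),
    seq = c("MADKTGTLLA", "GGDKTGTWYC", "CWDKTGTAAG",
            "MAGLLWYCAA", "GGPQRSTWYC", "CCAAGGLLMM"),
    label = c("+1", "+1", "+1", "-1", "-1", "-1"))
}

# helices as a tibble: n helices of length 21 separated by 30-residue loops
make_helices <- function(n, start = 30, hlen = 21, loop = 30) {
  s <- start + (seq_len(n) - 1) * (hlen + loop)
  tibble::tibble(start = s, end = s + hlen - 1)
}

# motif position in the loop after helix `after`
pos_after_helix <- function(helices, after, offset = 5) {
  helices$end[after] + offset
}
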