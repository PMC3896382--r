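test_that("binary generation plants motifs in positives only", {
  spec <- synthetic_spec(n_per_class = 30, n_negatives = 100,
                         length_range = c(80, 120), motif_presence = 1,
                         fragment_fraction = 0, substitution_noise = 0,
                         seed = 4)
  g <- generate_binary(spec)
  expect_equal(nrow(g$sequences), 130)
  pos <- g$sequences$label == "+1"
  expect_true(all(grepl("WDKTGTLW", g$sequences$seq[pos], fixed = TRUE)))
  expect_false(any(grepl("WDKTGTLW", g$sequences$seq[!pos], fixed = TRUE)))
  expect_true(all(g$manifest$planted[pos]))
  # planted positions are where the manifest says they are
  at <- substr(g$sequences$seq[pos], g$manifest$motif_pos[pos],
               g$manifest$motif_pos[pos] + 7)
  expect_true(all(at == "WDKTGTLW"))
})

test_that("identical spec and seed give byte-identical output", {
  spec <- synthetic_spec(n_per_class = 15, n_negatives = 40,
                         length_range = c(60, 90), seed = 33)
  g1 <- generate_binary(spec)
  g2 <- generate_binary(spec)
  expect_identical(g1, g2)
  f1 <- withr::local_tempfile()
  f2 <- withr::local_tempfile()
  write_fasta(g1$sequences, f1)
  write_fasta(g2$sequences, f2)
  expect_identical(unname(tools::md5sum(f1)), unname(tools::md5sum(f2)))
  g3 <- generate_binary(synthetic_spec(n_per_class = 15, n_negatives = 40,
                                       length_range = c(60, 90), seed = 34))
  expect_false(identical(g1$sequences$seq, g3$sequences$seq))
})

test_that("motif-bearing fraction tracks motif_presence within 3 binomial SDs", {
  n <- 400
  p <- 0.95
  g <- generate_binary(synthetic_spec(n_per_class = n, n_negatives = 1,
                                      length_range = c(100, 150),
                                      fragment_fraction = 0,
                                      substitution_noise = 0, seed = 19))
  frac <- mean(g$manifest$planted[g$manifest$label == "+1"])
  expect_lt(abs(frac - p), 3 * sqrt(p * (1 - p) / n))
})

test_that("substitution noise and fragmentation behave as configured", {
  spec <- synthetic_spec(n_per_class = 60, n_negatives = 10,
                         length_range = c(200, 200), motif_presence = 1,
                         fragment_fraction = 0.5, substitution_noise = 0.02,
                         seed = 6)
  g <- generate_binary(spec)
  frag <- g$manifest$fragment
  expect_gt(sum(frag), 10)  # ~half fragmented
  # fragments are 10-50% of the original 200 residues
  expect_true(all(g$manifest$length[frag] >= 20 &
                  g$manifest$length[frag] <= 100))
  expect_true(all(g$manifest$length[!frag] == 200))
  # noise flips roughly 2% of residues: compare a noiseless regeneration
  g0 <- generate_binary(synthetic_spec(n_per_class = 60, n_negatives = 10,
                                       length_range = c(200, 200),
                                       motif_presence = 1,
                                       fragment_fraction = 0.5,
                                       substitution_noise = 0, seed = 6))
  # compare positives only: they are generated before the noise draw, so the
  # two runs share their background residues (negatives are resampled later
  # in the RNG stream and differ wholesale)
  same_len <- !frag & !g0$manifest$fragment & g$manifest$label == "+1"
  diffs <- mapply(function(a, b) {
    sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
  }, g$sequences$seq[same_len], g0$sequences$seq[same_len])
  rate <- sum(diffs) / sum(nchar(g$sequences$seq[same_len]))
  expect_gt(rate, 0.01)
  expect_lt(rate, 0.03)
})

test_that("multiclass generation keeps classes identifiable and decoys clean", {
  spec <- synthetic_spec(n_classes = 11, n_per_class = 6, n_negatives = 15,
                         length_range = c(100, 160), seed = 13)
  g <- generate_multiclass(spec)
  expect_equal(nrow(g$sequences), 11 * 6 + 15)
  expect_equal(as.integer(table(g$manifest$true_class)[c("0", "IA")]),
               c(15L, 6L))
  # decoys carry zero planted-motif occurrences, of any class
  dec <- g$sequences$seq[g$manifest$true_class == "0"]
  for (mt in unlist(spec$motifs)) {
    expect_false(any(grepl(mt, dec, fixed = TRUE)))
  }
  # members never carry another class's motifs
  for (cl in names(spec$motifs)) {
    others <- unlist(spec$motifs[setdiff(names(spec$motifs), cl)])
    mine <- g$sequences$seq[g$manifest$true_class == cl]
    for (mt in others) expect_false(any(grepl(mt, mine, fixed = TRUE)))
  }
  expect_identical(generate_multiclass(spec), g)
})

test_that("cross-class substring motifs are rejected", {
  expect_error(synthetic_spec(n_classes = 2,
                              motifs = list(a = "WDKTGTLW", b = "DKTGT")),
               "substring")
  # within reason: a motif longer than its share of the minimum length fails
  expect_error(synthetic_spec(motifs = list("+1" = strrep("W", 500)),
                              length_range = c(400, 500)),
               "longer")
})

test_that("topology fixtures reproduce their answer key through assign_elements", {
  fx <- generate_topology_fixtures(seed = 2, per_category = 3)
  expect_setequal(unique(fx$expected$category),
                  c(topology_categories(), "unanchored"))
  topo <- assign_topology(fx$tm, fx$anchors)
  joined <- dplyr::inner_join(topo, fx$expected, by = "id")
  expect_equal(nrow(joined), nrow(fx$expected))
  expect_equal(joined$category.x, joined$category.y)
})
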