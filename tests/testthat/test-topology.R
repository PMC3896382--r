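test_that("assign_elements reproduces the canonical architectures", {
  # 10 helices, motif after M4 of the core: C-element of 4
  h10 <- make_helices(10)
  r <- assign_elements(h10, pos_after_helix(h10, 4))
  expect_equal(r[, c("n_count", "c_count", "category")],
               tibble::tibble(n_count = 0L, c_count = 4L, category = "core_C"))
  # 7 helices, one TM after the core
  h7 <- make_helices(7)
  expect_equal(assign_elements(h7, pos_after_helix(h7, 4))$category, "core_1TM")
  # 8 helices, motif after helix 6: N-element of 2
  h8 <- make_helices(8)
  r8 <- assign_elements(h8, pos_after_helix(h8, 6))
  expect_equal(r8$n_count, 2L)
  expect_equal(r8$c_count, 0L)
  expect_equal(r8$category, "N_core")
  # 12 helices, motif after helix 6: both elements
  h12 <- make_helices(12)
  r12 <- assign_elements(h12, pos_after_helix(h12, 6))
  expect_equal(r12$category, "N_core_C")
  expect_equal(c(r12$n_count, r12$c_count), c(2L, 4L))
  # exact 6-helix core
  h6 <- make_helices(6)
  expect_equal(assign_elements(h6, pos_after_helix(h6, 4))$category, "core_only")
  # fewer than 6 helices for the core
  h5 <- make_helices(5)
  expect_equal(assign_elements(h5, pos_after_helix(h5, 4))$category, "broken_core")
  # no anchor motif
  expect_equal(assign_elements(h10, NA)$category, "unanchored")
})

test_that("helix-count conservation holds for intact-core records", {
  for (n in 6:14) {
    for (after in 4:(n - 2)) {
      h <- make_helices(n)
      r <- assign_elements(h, pos_after_helix(h, after))
      if (r$category != "broken_core") {
        expect_equal(r$n_count + 6L + r$c_count, n)
      }
    }
  }
})

test_that("a helix containing the motif counts as before it, with a warning", {
  h <- make_helices(10)
  inside <- h$start[4] + 3  # inside helix 4
  r <- assign_elements(h, inside)
  expect_match(r$warnings, "motif_in_helix")
  expect_equal(r$m, 4L)
  expect_equal(r$category, "core_C")
})

test_that("the decomposition is translation invariant", {
  h <- make_helices(10)
  pos <- pos_after_helix(h, 4)
  base <- assign_elements(h, pos)
  shifted <- assign_elements(dplyr::mutate(h, start = start + 137,
                                           end = end + 137), pos + 137)
  expect_equal(shifted[, c("m", "n_count", "c_count", "category")],
               base[, c("m", "n_count", "c_count", "category")])
})

test_that("overlapping helix intervals are rejected", {
  bad <- tibble::tibble(start = c(10, 25), end = c(30, 50))
  expect_error(assign_elements(bad, 100), "overlap")
})

test_that("assign_topology joins TM tables with anchors and flags extras", {
  h <- make_helices(10)
  tm <- dplyr::bind_rows(dplyr::mutate(h, id = "withmotif"),
                         dplyr::mutate(h, id = "nomotif"))[, c("id", "start", "end")]
  anchors <- tibble::tibble(id = "withmotif",
                            motif_pos = pos_after_helix(h, 4),
                            extra_hits = "400")
  topo <- assign_topology(tm, anchors)
  expect_equal(topo$category[topo$id == "withmotif"], "core_C")
  expect_equal(topo$category[topo$id == "nomotif"], "unanchored")
  expect_match(topo$warnings[topo$id == "withmotif"], "extra_motif_hits=400")
})

test_that("motif_anchors uses the first hit and lists the rest", {
  a <- motif_anchors(c(two = "XXDKTGTXXXXDKTGTXX", none = "AAAA"))
  expect_equal(a$motif_pos[a$id == "two"], 3L)
  expect_equal(a$extra_hits[a$id == "two"], "12")
  expect_true(is.na(a$motif_pos[a$id == "none"]))
})

test_that("topology_summary tallies categories by class with totals", {
  h10 <- make_helices(10)
  h6 <- make_helices(6)
  recs <- dplyr::bind_rows(
    purrr::map_dfr(paste0("a", 1:3), function(i) {
      dplyr::mutate(assign_elements(h10, pos_after_helix(h10, 4)), id = i)
    }),
    dplyr::mutate(assign_elements(h6, pos_after_helix(h6, 4)), id = "b1"),
    dplyr::mutate(assign_elements(h10, NA), id = "u1"))
  classes <- tibble::tibble(id = c(paste0("a", 1:3), "b1", "u1"),
                            class = c("IIA", "IIA", "IIA", "IB", "0"))
  s <- topology_summary(recs, classes)
  expect_equal(s$core_C[s$class == "IIA"], 3L)
  expect_equal(s$core_only[s$class == "IB"], 1L)
  # grand total counts anchored records only; unanchored tracked separately
  expect_equal(s$Total[s$class == "Total"], 4L)
  expect_equal(attr(s, "n_unanchored"), 1L)
  expect_equal(sum(s$Total[s$class != "Total"]), s$Total[s$class == "Total"])
  # a record without a class is an error
  expect_error(topology_summary(recs, classes[-1, ]), "a1")
})

test_that("every record receives exactly one category", {
  fx <- generate_topology_fixtures(seed = 8, per_category = 2)
  topo <- assign_topology(fx$tm, fx$anchors)
  expect_equal(nrow(topo), length(unique(fx$tm$id)))
  expect_true(all(topo$category %in%
                  c(topology_categories(), "unanchored")))
})
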