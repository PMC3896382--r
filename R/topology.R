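#' Decompose a transmembrane topology into N-element / core / C-element
#'
#' P-type ATPase membrane domains decompose into three elements: a core of
#' six transmembrane helices (M1-M6) common to all pumps, and optional
#' N- and C-terminal helix elements. The decomposition is anchored on the
#' phosphorylation motif, which sits in the cytosolic loop after core helix
#' M4: with `m` helices ending before the motif position, the core is
#' helices `m - 3` to `m + 2`, the N-element the `m - 4` helices preceding
#' it and the C-element whatever follows. Architectures are then
#' categorized as `core_only`, `N_core` (N-element only), `core_C`
#' (C-element of 2+ helices), `N_core_C` (both), `core_1TM` (exactly one
#' helix after the core, no N-element), or `broken_core` when fewer than 6
#' helices remain for the core (`m < 4`, e.g. N-terminally truncated
#' fragments, or fewer than 2 helices after the motif). A sequence without
#' an anchor motif is `unanchored` — extra bookkeeping outside the six
#' structural categories.
#'
#' A helix interval that contains the motif position counts as being before
#' the motif and adds a `motif_in_helix` warning (in real pumps the motif
#' is cytosolic, so this only occurs with noisy predictions). The
#' decomposition is invariant under shifting all coordinates by a constant.
#'
#' @param helices Data frame of 1-based inclusive intervals (`start`,
#'   `end`), non-overlapping; sorted internally.
#' @param motif_pos 1-based position of the motif's first residue (the D of
#'   DKTGT), or `NA` when no motif was found.
#' @return One-row tibble: `total_helices`, `motif_pos`, `m`, `n_count`,
#'   `c_count`, `category`, `warnings`.
#' @export
#' @examples
#' h <- tibble::tibble(start = seq(1, 271, by = 30), end = seq(21, 291, by = 30))
#' assign_elements(h, motif_pos = 140) # 10 helices, motif after helix 4
assign_elements <- function(helices, motif_pos) {
  helices <- dplyr::arrange(tibble::as_tibble(helices), .data$start)
  total <- nrow(helices)
  if (total > 1 && any(helices$start[-1] <= helices$end[-total])) {
    abort("overlapping helix intervals")
  }
  if (any(helices$end < helices$start)) abort("helix interval with end < start")
  warnings <- character()
  if (is.na(motif_pos)) {
    return(tibble::tibble(total_helices = total, motif_pos = NA_integer_,
                          m = NA_integer_, n_count = NA_integer_,
                          c_count = NA_integer_, category = "unanchored",
                          warnings = ""))
  }
  inside <- helices$start <= motif_pos & helices$end >= motif_pos
  if (any(inside)) warnings <- c(warnings, "motif_in_helix")
  m <- sum(helices$end < motif_pos) + sum(inside)
  if (m < 4 || total < m + 2) {
    n_count <- NA_integer_
    c_count <- NA_integer_
    category <- "broken_core"
  } else {
    n_count <- m - 4L
    c_count <- total - (m + 2L)
    category <- dplyr::case_when(
      n_count == 0 & c_count == 0 ~ "core_only",
      n_count == 0 & c_count == 1 ~ "core_1TM",
      n_count >= 1 & c_count == 0 ~ "N_core",
      n_count == 0 & c_count >= 2 ~ "core_C",
      TRUE ~ "N_core_C")
  }
  tibble::tibble(total_helices = total, motif_pos = as.integer(motif_pos),
                 m = as.integer(m), n_count = as.integer(n_count),
                 c_count = as.integer(c_count), category = category,
                 warnings = paste(warnings, collapse = ";"))
}

topology_categories <- function() {
  c("core_only", "N_core", "core_C", "N_core_C", "core_1TM", "broken_core")
}

#' Locate the anchor motif in each sequence
#'
#' Exact-match positions of the anchor motif; when several hits exist the
#' first (lowest position) anchors the decomposition and the extras are
#' listed in a warning field.
#'
#' @param data Sequence tibble or character vector.
#' @param motif Anchor motif, default [dktgt_motif()].
#' @return Tibble: `id`, `motif_pos` (`NA` when absent), `n_hits`,
#'   `extra_hits` (comma-separated positions beyond the first).
#' @export
motif_anchors <- function(data, motif = dktgt_motif()) {
  ids <- pull_ids(data)
  hits <- scan_motif(data, motif, max_mismatch = 0)
  per_id <- hits |>
    dplyr::group_by(id = .data$id) |>
    dplyr::summarise(motif_pos = min(.data$position),
                     n_hits = dplyr::n(),
                     extra_hits = paste(sort(.data$position)[-1], collapse = ","),
                     .groups = "drop")
  tibble::tibble(id = ids) |>
    dplyr::left_join(per_id, by = "id") |>
    dplyr::mutate(n_hits = dplyr::coalesce(.data$n_hits, 0L),
                  extra_hits = dplyr::coalesce(.data$extra_hits, ""))
}

#' Topology decomposition for a table of proteins
#'
#' Applies [assign_elements()] to every id in a TM-interval table, using
#' the supplied anchors (e.g. from [motif_anchors()]).
#'
#' @param tm TM-interval tibble (`id`, `start`, `end`), as returned by
#'   [read_tm_table()].
#' @param anchors Tibble with `id` and `motif_pos` (and optionally
#'   `extra_hits`); ids absent from it are treated as unanchored.
#' @return Tibble with one row per id: the [assign_elements()] fields plus
#'   `id`.
#' @export
assign_topology <- function(tm, anchors) {
  ids <- unique(tm$id)
  anchors <- tibble::as_tibble(anchors)
  purrr::map_dfr(ids, function(i) {
    h <- tm[tm$id == i, c("start", "end")]
    a <- anchors[anchors$id == i, ]
    pos <- if (nrow(a) == 0) NA_integer_ else a$motif_pos[1]
    rec <- assign_elements(h, pos)
    if (nrow(a) > 0 && "extra_hits" %in% names(a) && nzchar(a$extra_hits[1])) {
      extra <- paste0("extra_motif_hits=", a$extra_hits[1])
      rec$warnings <- ifelse(nzchar(rec$warnings),
                             paste(rec$warnings, extra, sep = ";"), extra)
    }
    dplyr::mutate(rec, id = i, .before = 1)
  })
}

#' Category-by-class topology summary
#'
#' Contingency table of topology categories (columns) by assigned class
#' (rows, class `"0"` first then `class_list` order), with row and column
#' totals. Unanchored records fall outside the six structural categories;
#' they are excluded from the table and counted in the `n_unanchored`
#' attribute.
#'
#' @param records Topology tibble from [assign_topology()].
#' @param classes Tibble mapping `id` to `class` (class `"0"` allowed).
#' @param class_list Ordered class list, default [ptype_classes()].
#' @return Tibble with one row per class plus a `Total` row; attribute
#'   `n_unanchored` carries the number of excluded records.
#' @export
topology_summary <- function(records, classes, class_list = ptype_classes()) {
  classes <- tibble::as_tibble(classes)
  missing <- setdiff(records$id, classes$id)
  if (length(missing) > 0) {
    abort(paste0("no class for id(s): ",
                 paste(utils::head(missing, 10), collapse = ", ")))
  }
  joined <- dplyr::left_join(records, classes, by = "id")
  bad <- setdiff(unique(joined$class), c("0", class_list))
  if (length(bad) > 0) {
    abort(paste0("class(es) outside the class list: ", paste(bad, collapse = ", ")))
  }
  n_unanchored <- sum(joined$category == "unanchored")
  anchored <- dplyr::filter(joined, .data$category != "unanchored")
  rows <- c("0", class_list)
  cats <- topology_categories()
  tab <- anchored |>
    dplyr::count(.data$class, .data$category) |>
    tidyr::pivot_wider(names_from = "category", values_from = "n",
                       values_fill = 0L)
  for (cat in setdiff(cats, names(tab))) tab[[cat]] <- 0L
  out <- tibble::tibble(class = rows) |>
    dplyr::left_join(tab, by = "class") |>
    dplyr::mutate(dplyr::across(dplyr::all_of(cats), ~ dplyr::coalesce(.x, 0L))) |>
    dplyr::select(dplyr::all_of(c("class", cats))) |>
    dplyr::mutate(Total = rowSums(dplyr::pick(dplyr::all_of(cats))))
  total_row <- dplyr::summarise(
    out, class = "Total",
    dplyr::across(dplyr::all_of(c(cats, "Total")), sum))
  out <- dplyr::bind_rows(out, total_row)
  attr(out, "n_unanchored") <- n_unanchored
  out
}
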