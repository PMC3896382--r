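#' Flag sequences with unusual lengths
#'
#' Members of the target family are typically between `soft_min` and
#' `soft_max` residues long; anything outside gets a `length_short` or
#' `length_long` flag, and sequences under `hard_min` residues (in
#' practice, spurious hits such as short virus envelope fragments) get an
#' additional `hard_short` removal-candidate flag. Curation emits flags
#' only — no sequence is ever filtered or deleted, so classification
#' results are identical with curation on or off; removal is a user action
#' via an exclusion list.
#'
#' @param data Sequence tibble.
#' @param soft_min,soft_max Expected length band (defaults 600 and 2000).
#' @param hard_min Removal-candidate threshold (default 50).
#' @return Tibble of flags: `id`, `flag`, `detail`.
#' @export
flag_lengths <- function(data, soft_min = 600, soft_max = 2000, hard_min = 50) {
  len <- nchar(pull_seqs(data))
  id <- pull_ids(data)
  detail <- paste0("length=", len)
  dplyr::bind_rows(
    tibble::tibble(id = id[len < soft_min], flag = "length_short",
                   detail = detail[len < soft_min]),
    tibble::tibble(id = id[len > soft_max], flag = "length_long",
                   detail = detail[len > soft_max]),
    tibble::tibble(id = id[len < hard_min], flag = "hard_short",
                   detail = detail[len < hard_min])) |>
    dplyr::arrange(.data$id)
}

#' Scan sequences for a motif, allowing point mutations
#'
#' Reports every window of length `nchar(motif)` whose Hamming distance to
#' the motif is at most `max_mismatch` (substitutions only — single point
#' mutations, not indels), with 1-based positions in ascending order. The
#' scan is exhaustive over all `len - nchar(motif) + 1` windows; with
#' `max_mismatch = 0` it reduces to plain substring search.
#'
#' @param data Sequence tibble or character vector.
#' @param motif Motif string, default [dktgt_motif()].
#' @param max_mismatch Maximum substitutions per window (default 1; must be
#'   smaller than the motif length).
#' @return Tibble of hits: `id`, `position`, `matched`, `n_mismatch`.
#'   Sequences with no hit (including those shorter than the motif) have no
#'   rows; see [flag_motifs()] for the `motif_absent` marking.
#' @export
#' @examples
#' scan_motif(c(a = "AADKTGTAA", b = "AADKTGSAA", c = "AAAAA"))
scan_motif <- function(data, motif = dktgt_motif(), max_mismatch = 1) {
  stopifnot(nzchar(motif), max_mismatch >= 0, max_mismatch < nchar(motif))
  seqs <- pull_seqs(data)
  ids <- pull_ids(data)
  subj <- Biostrings::BStringSet(setNames(seqs, ids))
  hits <- Biostrings::vmatchPattern(motif, subj, max.mismatch = max_mismatch,
                                    with.indels = FALSE, fixed = TRUE)
  m <- nchar(motif)
  motif_chars <- strsplit(motif, "")[[1]]
  empty <- tibble::tibble(id = character(), position = integer(),
                          matched = character(), n_mismatch = integer())
  out <- purrr::map_dfr(seq_along(hits), function(i) {
    r <- hits[[i]]
    if (length(r) == 0) return(NULL)
    st <- BiocGenerics::start(r)
    # drop partial out-of-bound hits: windows must lie fully inside
    keep <- st >= 1 & (st + m - 1) <= nchar(seqs[i])
    st <- sort(st[keep])
    if (length(st) == 0) return(NULL)
    matched <- stringr::str_sub(seqs[i], st, st + m - 1)
    nmm <- vapply(matched, function(w) {
      sum(strsplit(w, "")[[1]] != motif_chars)
    }, integer(1), USE.NAMES = FALSE)
    tibble::tibble(id = ids[i], position = st, matched = matched,
                   n_mismatch = nmm)
  })
  if (nrow(out) == 0) empty else out
}

#' Derive per-site motif flags from a scan
#'
#' Exact hits are flagged `motif_exact`, mutated hits `motif_variant`
#' (mutually exclusive per site), and sequences with no window within
#' `max_mismatch` get a single `motif_absent` flag. Variant sites are
#' candidates for external homology review, which is outside this
#' package's scope; the detail field marks them `needs external review`.
#'
#' @inheritParams scan_motif
#' @return Flag tibble: `id`, `flag`, `detail`.
#' @export
flag_motifs <- function(data, motif = dktgt_motif(), max_mismatch = 1) {
  ids <- pull_ids(data)
  hits <- scan_motif(data, motif, max_mismatch)
  site_flags <- if (nrow(hits) == 0) {
    tibble::tibble(id = character(), flag = character(), detail = character())
  } else {
    dplyr::transmute(
      hits, id = .data$id,
      flag = ifelse(.data$n_mismatch == 0, "motif_exact", "motif_variant"),
      detail = ifelse(.data$n_mismatch == 0,
                      paste0("pos=", .data$position),
                      paste0("pos=", .data$position, " ", .data$matched,
                             " needs external review")))
  }
  absent <- setdiff(ids, unique(hits$id))
  dplyr::bind_rows(site_flags,
                   tibble::tibble(id = absent, flag = "motif_absent",
                                  detail = "")) |>
    dplyr::arrange(.data$id)
}

#' Join classification records with curation flags
#'
#' Produces the reviewable curation table: one row per (record, flag) pair
#' in ascending id order (unflagged records keep one row with an empty
#' flag), plus per-(class, flag) counts. Flags referring to ids absent from
#' the records are an error.
#'
#' @param records Classification tibble from [classify_sequences()] (needs
#'   `id` and `assigned`).
#' @param flags Flag tibble from [flag_lengths()] / [flag_motifs()].
#' @return List with `rows` (the joined table) and `counts` (class-by-flag
#'   tallies).
#' @export
curation_report <- function(records, flags) {
  orphans <- setdiff(flags$id, records$id)
  if (length(orphans) > 0) {
    abort(paste0("flag id(s) not present in the classification records: ",
                 paste(utils::head(orphans, 10), collapse = ", ")))
  }
  rows <- records |>
    dplyr::select("id", "assigned") |>
    dplyr::left_join(flags, by = "id") |>
    dplyr::mutate(flag = dplyr::coalesce(.data$flag, ""),
                  detail = dplyr::coalesce(.data$detail, "")) |>
    dplyr::arrange(.data$id)
  counts <- rows |>
    dplyr::filter(nzchar(.data$flag)) |>
    dplyr::count(.data$assigned, .data$flag, name = "n") |>
    dplyr::arrange(.data$assigned, .data$flag)
  list(rows = rows, counts = counts)
}
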