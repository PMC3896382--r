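#' Read protein sequences from FASTA, with an optional label manifest
#'
#' Sequences are case-folded to upper case and validated against
#' [amino_alphabet()]. Labels live in a sidecar two-column tab-separated
#' file (`id<TAB>label`, no header) rather than in FASTA headers, which
#' keeps the FASTA file standard-compliant. Sequences without a label entry
#' are marked `"unlabeled"`. The id of a record is the first
#' whitespace-delimited token of its header line.
#'
#' @param path Path to a FASTA file.
#' @param labels Optional path to the label manifest. Allowed labels are
#'   `"+1"`, `"-1"`, `"unlabeled"`, or a class name from `classes`.
#' @param classes Class names accepted in multiclass manifests; defaults to
#'   [ptype_classes()].
#' @return A tibble with columns `id`, `seq`, `label`.
#' @export
#' @examples
#' fa <- tempfile(fileext = ".fasta")
#' writeLines(c(">a", "mvdktgt"), fa)
#' read_fasta(fa)
read_fasta <- function(path, labels = NULL, classes = ptype_classes()) {
  # BStringSet rather than AAStringSet: we do our own alphabet validation so
  # that a violation can be reported with the offending record's id
  x <- Biostrings::readBStringSet(path)
  if (length(x) == 0) abort(paste0("FASTA file is empty: ", path))
  ids <- stringr::str_split_i(names(x), "\\s+", 1)
  if (anyDuplicated(ids)) {
    abort(paste0("duplicate sequence id(s) in ", path, ": ",
                 paste(unique(ids[duplicated(ids)]), collapse = ", ")))
  }
  seqs <- toupper(as.character(x))
  bad <- !stringr::str_detect(seqs, alphabet_regex())
  if (any(bad)) {
    first <- which(bad)[1]
    offending <- setdiff(unique(strsplit(seqs[first], "")[[1]]), amino_alphabet())
    abort(paste0("record \"", ids[first], "\" contains characters outside the ",
                 "amino-acid alphabet: ", paste(offending, collapse = " ")))
  }
  out <- tibble::tibble(id = ids, seq = unname(seqs), label = "unlabeled")
  if (!is.null(labels)) {
    lab <- read_labels(labels, classes = classes)
    orphan <- setdiff(lab$id, out$id)
    if (length(orphan) > 0) {
      abort(paste0("label manifest mentions id(s) absent from the FASTA: ",
                   paste(utils::head(orphan, 5), collapse = ", ")))
    }
    idx <- match(out$id, lab$id)
    out$label[!is.na(idx)] <- lab$label[idx[!is.na(idx)]]
  }
  out
}

#' Read a label manifest
#'
#' @param path Two-column TSV (`id`, `label`), no header.
#' @inheritParams read_fasta
#' @return Tibble with columns `id`, `label`.
#' @export
read_labels <- function(path, classes = ptype_classes()) {
  lab <- readr::read_tsv(path, col_names = c("id", "label"),
                         col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  allowed <- c("+1", "-1", "unlabeled", classes)
  bad <- setdiff(unique(lab$label), allowed)
  if (length(bad) > 0) {
    abort(paste0("unknown label name(s): ", paste(bad, collapse = ", "),
                 " (allowed: +1, -1, unlabeled, or a configured class name)"))
  }
  if (anyDuplicated(lab$id)) {
    abort("duplicate id(s) in label manifest")
  }
  lab
}

#' Write sequences to FASTA / labels to a manifest
#'
#' @param data Tibble with `id` and `seq` (and for `write_labels`, `label`).
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(data, path) {
  x <- Biostrings::BStringSet(setNames(data$seq, data$id))
  Biostrings::writeXStringSet(x, path, width = 70L)
  invisible(path)
}

#' @rdname write_fasta
#' @export
write_labels <- function(data, path) {
  readr::write_tsv(data[, c("id", "label")], path, col_names = FALSE,
                   progress = FALSE)
  invisible(path)
}

#' Read a transmembrane-helix interval table
#'
#' Consumes the tabular output of a TM-topology predictor (e.g. the helix
#' intervals reported by Phobius): a headerless TSV with columns `id`,
#' `start`, `end`. Coordinates are 1-based inclusive residue positions, the
#' residue-numbering convention of structural biology. Intervals are
#' returned sorted by start within each id; overlapping or reversed
#' intervals are rejected.
#'
#' @param path Path to the TSV file.
#' @return Tibble with columns `id`, `start`, `end`.
#' @export
read_tm_table <- function(path) {
  raw <- readr::read_tsv(path, col_names = c("id", "start", "end"),
                         col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  for (col in c("start", "end")) {
    v <- suppressWarnings(as.numeric(raw[[col]]))
    bad <- is.na(v) | v != floor(v)
    if (any(bad)) {
      abort(paste0("non-integer ", col, " coordinate at line ", which(bad)[1],
                   " of ", path))
    }
    raw[[col]] <- as.integer(v)
  }
  rev <- raw$end < raw$start
  if (any(rev)) {
    abort(paste0("interval with end < start at line ", which(rev)[1], " of ", path))
  }
  out <- dplyr::arrange(raw, .data$id, .data$start)
  ovl <- out |>
    dplyr::group_by(.data$id) |>
    dplyr::summarise(overlap = dplyr::n() > 1 &&
                       any(.data$start[-1] <= .data$end[-dplyr::n()]),
                     .groups = "drop")
  if (any(ovl$overlap)) {
    abort(paste0("overlapping TM intervals for id(s): ",
                 paste(ovl$id[ovl$overlap], collapse = ", ")))
  }
  out
}
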