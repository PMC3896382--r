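#' Specification for synthetic benchmark data
#'
#' Describes a labeled sequence population with known ground truth: i.i.d.
#' background residues with one or more class-specific motifs planted into
#' class members, a configurable positive/negative imbalance, uniform
#' length variation, optional truncation to fragments, and light
#' post-planting substitution noise. The generator emulates the structure
#' of a needle-in-a-haystack protein-family screen (a few hundred family
#' members among tens of thousands of unrelated proteins); it makes no
#' attempt to mimic real residue composition or phylogenetic correlation.
#'
#' @param n_classes Number of classes (1 = binary positives vs negatives).
#' @param motifs Named list, class name -> character vector of planted
#'   motifs. Defaults: a single `"WDKTGTLW"` 8-mer for binary specs, and
#'   [default_class_motifs()] for 11-class specs. Motifs of different
#'   classes must not be substrings of one another (identifiability).
#' @param motif_presence Probability that a class member carries each of
#'   its class motifs (default 0.95, drawn independently per motif).
#' @param background Residue frequencies over the 20 standard amino acids;
#'   default uniform.
#' @param length_range Sequence length bounds, uniform integer draw
#'   (default 400-1200 residues).
#' @param n_per_class Class members generated per class.
#' @param n_negatives Background-only sequences (binary negatives, or
#'   multiclass decoys whose ground truth is class `"0"`).
#' @param fragment_fraction Probability a sequence is truncated to a
#'   uniform 10-50% of its length, from either end (default 0.05) —
#'   emulating the sequence fragments found in real databases.
#' @param substitution_noise Per-residue substitution probability applied
#'   after motif planting (default 0.005); substitutions always change the
#'   residue.
#' @param seed Integer seed; identical spec and seed give byte-identical
#'   output.
#' @return A list of class `"synthetic_spec"`.
#' @export
synthetic_spec <- function(n_classes = 1, motifs = NULL, motif_presence = 0.95,
                           background = NULL, length_range = c(400, 1200),
                           n_per_class = 200, n_negatives = 2000,
                           fragment_fraction = 0.05, substitution_noise = 0.005,
                           seed = 1L) {
  if (is.null(motifs)) {
    motifs <- if (n_classes == 1) list("+1" = "WDKTGTLW")
              else if (n_classes == 11) default_class_motifs()
              else abort("supply `motifs` for a custom class count")
  }
  if (length(motifs) != n_classes) abort("need one motif set per class")
  if (is.null(names(motifs)) || any(!nzchar(names(motifs)))) {
    abort("`motifs` must be a named list (class name -> motif strings)")
  }
  all_motifs <- unlist(motifs)
  if (any(!nzchar(all_motifs)) ||
      any(!stringr::str_detect(toupper(all_motifs), alphabet_regex()))) {
    abort("motifs must be non-empty strings over the amino-acid alphabet")
  }
  # cross-class substring overlap breaks identifiability
  cls_of <- rep(names(motifs), lengths(motifs))
  for (i in seq_along(all_motifs)) {
    for (j in seq_along(all_motifs)) {
      if (cls_of[i] != cls_of[j] &&
          stringr::str_detect(all_motifs[j], stringr::fixed(all_motifs[i]))) {
        abort(paste0("motif \"", all_motifs[i], "\" (class ", cls_of[i],
                     ") is a substring of \"", all_motifs[j], "\" (class ",
                     cls_of[j], ")"))
      }
    }
  }
  stopifnot(motif_presence >= 0, motif_presence <= 1,
            fragment_fraction >= 0, fragment_fraction <= 1,
            substitution_noise >= 0, substitution_noise <= 1,
            length(length_range) == 2, length_range[1] <= length_range[2],
            n_per_class >= 1, n_negatives >= 0)
  if (is.null(background)) {
    background <- setNames(rep(1 / 20, 20), aa_standard())
  }
  slot <- floor(length_range[1] / max(lengths(motifs)))
  if (max(nchar(all_motifs)) > slot) {
    abort("motif longer than the per-motif share of the minimum sequence length")
  }
  structure(list(n_classes = n_classes, motifs = lapply(motifs, toupper),
                 motif_presence = motif_presence, background = background,
                 length_range = as.integer(length_range),
                 n_per_class = as.integer(n_per_class),
                 n_negatives = as.integer(n_negatives),
                 fragment_fraction = fragment_fraction,
                 substitution_noise = substitution_noise,
                 seed = as.integer(seed)),
            class = "synthetic_spec")
}

#' Default planted motifs for the 11-class benchmark
#'
#' Two distinct 8-mers per class, drawn once from a fixed internal seed so
#' the defaults are stable across sessions. Equal length plus distinctness
#' guarantees the pairwise non-substring identifiability requirement. Two
#' motifs per class mirror real subfamilies, which carry several
#' independently conserved signature segments; with presence 0.95 per
#' motif, only ~0.25% of class members end up with no class signal at all.
#'
#' @param classes Class names, default [ptype_classes()].
#' @param n_motifs Motifs per class (default 2).
#' @param motif_length Motif length (default 8).
#' @return Named list of character vectors.
#' @export
default_class_motifs <- function(classes = ptype_classes(), n_motifs = 2,
                                 motif_length = 8) {
  total <- length(classes) * n_motifs
  motifs <- withr::with_seed(104729, {
    out <- character(0)
    while (length(out) < total) {
      cand <- paste(sample(aa_standard(), motif_length, replace = TRUE),
                    collapse = "")
      if (!cand %in% out) out <- c(out, cand)
    }
    out
  })
  setNames(split(motifs, rep(seq_along(classes), each = n_motifs)), classes)
}

# --- internals --------------------------------------------------------------

# background residues for n sequences of the given lengths, as one flat
# character vector (vectorized generation; sliced into strings later)
draw_background <- function(total, background) {
  sample(names(background), total, replace = TRUE, prob = background)
}

flat_to_seqs <- function(chars, lengths) {
  big <- stringr::str_flatten(chars)
  ends <- cumsum(lengths)
  stringr::str_sub(big, ends - lengths + 1, ends)
}

mutate_residues <- function(chars, rate, letters) {
  if (rate <= 0) return(chars)
  idx <- which(runif(length(chars)) < rate)
  if (length(idx) == 0) return(chars)
  repl <- sample(letters, length(idx), replace = TRUE)
  clash <- repl == chars[idx]
  while (any(clash)) {
    repl[clash] <- sample(letters, sum(clash), replace = TRUE)
    clash <- repl == chars[idx]
  }
  chars[idx] <- repl
  chars
}

# plant each motif of `motifs_vec` independently with prob `presence` into
# its own length slot (slot j = j-th fraction of the sequence), so planted
# motifs never overwrite each other; returns modified chars + plant table
plant_motifs <- function(chars, starts, lengths, motifs_vec, presence) {
  n <- length(lengths)
  k <- length(motifs_vec)
  plants <- vector("list", k)
  for (j in seq_len(k)) {
    m <- nchar(motifs_vec[j])
    slot_lo <- floor((j - 1) * lengths / k) + 1
    slot_hi <- floor(j * lengths / k) - m + 1
    carry <- runif(n) < presence
    pos <- slot_lo + floor(runif(n) * (slot_hi - slot_lo + 1))
    mot_chars <- strsplit(motifs_vec[j], "")[[1]]
    sel <- which(carry)
    if (length(sel) > 0) {
      gidx <- rep(starts[sel] + pos[sel] - 1, each = m) +
        rep(seq_len(m) - 1, times = length(sel))
      chars[gidx] <- rep(mot_chars, times = length(sel))
    }
    plants[[j]] <- tibble::tibble(motif = motifs_vec[j], planted = carry,
                                  position = ifelse(carry, pos, NA_integer_),
                                  seq_index = seq_len(n))
  }
  list(chars = chars, plants = dplyr::bind_rows(plants))
}

# resample any sequence containing a forbidden motif until clean
reject_motifs <- function(seqs, lengths, forbidden, background) {
  has_any <- function(x) {
    hit <- rep(FALSE, length(x))
    for (mt in forbidden) hit <- hit | stringr::str_detect(x, stringr::fixed(mt))
    hit
  }
  bad <- which(has_any(seqs))
  guard <- 0
  while (length(bad) > 0 && guard < 100) {
    for (i in bad) {
      seqs[i] <- paste(draw_background(lengths[i], background), collapse = "")
    }
    bad <- bad[has_any(seqs[bad])]
    guard <- guard + 1
  }
  seqs
}

apply_fragments <- function(seqs, fraction) {
  n <- length(seqs)
  sel <- runif(n) < fraction
  keep <- runif(n, 0.1, 0.5)
  from_start <- runif(n) < 0.5
  len <- nchar(seqs)
  newlen <- pmax(1L, as.integer(floor(len * keep)))
  out <- seqs
  i <- which(sel & from_start)
  out[i] <- stringr::str_sub(seqs[i], 1, newlen[i])
  i <- which(sel & !from_start)
  out[i] <- stringr::str_sub(seqs[i], len[i] - newlen[i] + 1, len[i])
  list(seqs = out, fragment = sel)
}

gen_lengths <- function(n, range) {
  range[1] + floor(runif(n) * (range[2] - range[1] + 1))
}

#' Generate a binary benchmark dataset with planted motifs
#'
#' Positives are background sequences carrying the planted motif(s) with
#' probability `motif_presence` at a uniform random position; negatives are
#' pure background, rejection-sampled so that none contains a planted
#' motif. Substitution noise is applied after planting (so a planted motif
#' can be mutated), then fragmentation. Identical spec and seed give
#' byte-identical output.
#'
#' @param spec A [synthetic_spec()] with `n_classes = 1`.
#' @return List with `sequences` (tibble `id`, `seq`, `label`) and
#'   `manifest` (ground truth: planted motif positions, fragment status,
#'   and post-hoc `has_motif`).
#' @export
#' @examples
#' d <- generate_binary(synthetic_spec(n_per_class = 5, n_negatives = 10,
#'                                     length_range = c(60, 80), seed = 7))
#' d$sequences
generate_binary <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"), spec$n_classes == 1)
  motifs_vec <- spec$motifs[[1]]
  withr::with_seed(spec$seed, {
    n_pos <- spec$n_per_class
    n_neg <- spec$n_negatives
    pos_len <- gen_lengths(n_pos, spec$length_range)
    neg_len <- gen_lengths(n_neg, spec$length_range)
    pos_chars <- draw_background(sum(pos_len), spec$background)
    starts <- cumsum(pos_len) - pos_len + 1
    planted <- plant_motifs(pos_chars, starts, pos_len, motifs_vec,
                            spec$motif_presence)
    pos_chars <- mutate_residues(planted$chars, spec$substitution_noise,
                                 names(spec$background))
    pos_seqs <- flat_to_seqs(pos_chars, pos_len)
    neg_seqs <- flat_to_seqs(draw_background(sum(neg_len), spec$background),
                             neg_len)
    neg_seqs <- reject_motifs(neg_seqs, neg_len, motifs_vec, spec$background)
    pos_frag <- apply_fragments(pos_seqs, spec$fragment_fraction)
    neg_frag <- apply_fragments(neg_seqs, spec$fragment_fraction)
    ids <- c(sprintf("pos%04d", seq_len(n_pos)),
             sprintf("neg%05d", seq_len(n_neg)))
    seqs <- c(pos_frag$seqs, neg_frag$seqs)
    first_plant <- planted$plants |>
      dplyr::filter(.data$motif == motifs_vec[1]) |>
      dplyr::arrange(.data$seq_index)
    has_motif <- rep(FALSE, length(seqs))
    for (mt in motifs_vec) {
      has_motif <- has_motif | stringr::str_detect(seqs, stringr::fixed(mt))
    }
    sequences <- tibble::tibble(id = ids, seq = seqs,
                                label = rep(c("+1", "-1"), c(n_pos, n_neg)))
    manifest <- tibble::tibble(
      id = ids, label = sequences$label,
      motif = c(rep(motifs_vec[1], n_pos), rep(NA_character_, n_neg)),
      planted = c(first_plant$planted, rep(FALSE, n_neg)),
      motif_pos = c(first_plant$position, rep(NA_integer_, n_neg)),
      fragment = c(pos_frag$fragment, neg_frag$fragment),
      length = nchar(seqs), has_motif = has_motif)
    list(sequences = sequences, manifest = manifest)
  })
}

#' Generate a multiclass benchmark dataset with decoys
#'
#' Each class member carries only its own class motifs (each planted
#' independently with probability `motif_presence`); decoys are pure
#' background, rejection-sampled to be free of every class motif, with
#' ground-truth class `"0"`. Decoys are returned with label `"unlabeled"`
#' in the sequence table since they carry no trainable class.
#'
#' @param spec A [synthetic_spec()] with `n_classes >= 2`.
#' @return List with `sequences` and `manifest` (column `true_class`).
#' @export
generate_multiclass <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"), spec$n_classes >= 2)
  classes <- names(spec$motifs)
  all_motifs <- unlist(spec$motifs)
  withr::with_seed(spec$seed, {
    per_class <- lapply(classes, function(cl) {
      n <- spec$n_per_class
      len <- gen_lengths(n, spec$length_range)
      chars <- draw_background(sum(len), spec$background)
      starts <- cumsum(len) - len + 1
      planted <- plant_motifs(chars, starts, len, spec$motifs[[cl]],
                              spec$motif_presence)
      chars <- mutate_residues(planted$chars, spec$substitution_noise,
                               names(spec$background))
      seqs <- flat_to_seqs(chars, len)
      # a member must not accidentally carry another class's motif
      other <- setdiff(all_motifs, spec$motifs[[cl]])
      for (mt in other) {
        bad <- which(stringr::str_detect(seqs, stringr::fixed(mt)))
        for (i in bad) {
          repeat {
            cand <- paste(draw_background(len[i], spec$background),
                          collapse = "")
            for (own in spec$motifs[[cl]]) {
              p <- floor(runif(1) * (len[i] - nchar(own))) + 1
              stringr::str_sub(cand, p, p + nchar(own) - 1) <- own
            }
            ok <- !any(vapply(other, function(o)
              stringr::str_detect(cand, stringr::fixed(o)), logical(1)))
            if (ok) break
          }
          seqs[i] <- cand
        }
      }
      frag <- apply_fragments(seqs, spec$fragment_fraction)
      tibble::tibble(id = sprintf("%s_%03d", cl, seq_len(n)),
                     seq = frag$seqs, label = cl, true_class = cl,
                     fragment = frag$fragment)
    })
    n_dec <- spec$n_negatives
    dec_len <- gen_lengths(n_dec, spec$length_range)
    dec <- flat_to_seqs(draw_background(sum(dec_len), spec$background), dec_len)
    dec <- reject_motifs(dec, dec_len, all_motifs, spec$background)
    dec_frag <- apply_fragments(dec, spec$fragment_fraction)
    decoys <- tibble::tibble(id = sprintf("decoy%04d", seq_len(n_dec)),
                             seq = dec_frag$seqs, label = "unlabeled",
                             true_class = "0", fragment = dec_frag$fragment)
    all <- dplyr::bind_rows(c(per_class, list(decoys)))
    has_class_motif <- rep(FALSE, nrow(all))
    for (cl in classes) {
      in_cl <- all$true_class == cl
      hit <- rep(FALSE, sum(in_cl))
      for (mt in spec$motifs[[cl]]) {
        hit <- hit | stringr::str_detect(all$seq[in_cl], stringr::fixed(mt))
      }
      has_class_motif[in_cl] <- hit
    }
    list(sequences = all[, c("id", "seq", "label")],
         manifest = tibble::tibble(id = all$id, true_class = all$true_class,
                                   fragment = all$fragment,
                                   length = nchar(all$seq),
                                   has_class_motif = has_class_motif))
  })
}

#' Generate transmembrane-topology fixtures with known categories
#'
#' Emits helix-interval tables covering every structural category —
#' `core_only` (6 helices), `N_core` (8), `core_C` (10), `N_core_C` (12),
#' `core_1TM` (7), `broken_core` (5) — plus `unanchored` (10 helices, no
#' motif), with randomized but consistent coordinates (helix length 19-23
#' residues, inter-helix loops of at least 8) and the anchor motif placed
#' in the loop after the appropriate core helix. The expected category of
#' each fixture is returned as an answer key.
#'
#' @param seed Integer seed.
#' @param per_category Fixtures per category (default 3).
#' @return List with `tm` (tibble `id`, `start`, `end`), `anchors` (tibble
#'   `id`, `motif_pos`; unanchored ids absent) and `expected` (tibble `id`,
#'   `category`).
#' @export
generate_topology_fixtures <- function(seed = 1, per_category = 3) {
  layout <- tibble::tribble(
    ~category, ~n_helix, ~anchor_helix,
    "core_only", 6L, 4L,
    "N_core", 8L, 6L,
    "core_C", 10L, 4L,
    "N_core_C", 12L, 6L,
    "core_1TM", 7L, 4L,
    "broken_core", 5L, 4L,
    "unanchored", 10L, NA_integer_)
  withr::with_seed(seed, {
    rows <- purrr::map_dfr(seq_len(nrow(layout)), function(i) {
      purrr::map_dfr(seq_len(per_category), function(r) {
        nh <- layout$n_helix[i]
        hlen <- sample(19:23, nh, replace = TRUE)
        loops <- sample(8:40, nh, replace = TRUE)
        start <- cumsum(loops) + cumsum(c(0, hlen[-nh]))
        end <- start + hlen - 1
        id <- sprintf("%s_%02d", layout$category[i], r)
        anchor <- layout$anchor_helix[i]
        motif_pos <- if (is.na(anchor)) NA_integer_
                     else end[anchor] + sample(2:6, 1)
        tibble::tibble(id = id, start = start, end = end,
                       motif_pos = motif_pos, category = layout$category[i])
      })
    })
    list(tm = rows[, c("id", "start", "end")],
         anchors = dplyr::distinct(rows[!is.na(rows$motif_pos),
                                        c("id", "motif_pos")]),
         expected = dplyr::distinct(rows[, c("id", "category")]))
  })
}
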