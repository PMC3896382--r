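#' Residue alphabet accepted by the package
#'
#' The 20 standard amino-acid letters plus the ambiguity/rare-residue codes
#' B, X, Z, U and O. Sequences are case-folded to upper case on input and any
#' other character is rejected. Ambiguity letters are treated verbatim: a
#' predictor containing `X` matches only a literal `X`, because the model
#' works on sequences as plain strings with no biochemical interpretation.
#'
#' @return Character vector of the 25 allowed single-letter codes.
#' @export
#' @examples
#' amino_alphabet()
amino_alphabet <- function() {
  c(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], "B", "X", "Z", "U", "O")
}

# standard residues only, used by the synthetic generator
aa_standard <- function() strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

alphabet_regex <- function() "^[ACDEFGHIKLMNPQRSTVWYBXZUO]+$"

#' Canonical P-type ATPase class list
#'
#' The 11 subfamilies of the P-type ATPase pump family (superclasses I-V),
#' in their conventional order. The order matters: it is the deterministic
#' tie-break used when two one-vs-all classifiers give the same probability,
#' and it fixes row/column ordering in summary tables.
#'
#' @return Character vector of 11 class names.
#' @export
#' @examples
#' ptype_classes()
ptype_classes <- function() {
  c("IA", "IB", "IIA", "IIB", "IIC", "IID", "IIIA", "IIIB", "IV", "VA", "VB")
}

#' The canonical phosphorylation-site motif
#'
#' The five-residue DKTGT motif whose aspartate forms the phosphoaspartate
#' intermediate that defines the P-type ATPase family. Used as the default
#' for motif curation and as the positional anchor for topology
#' decomposition (it sits in the cytosolic loop after core helix M4).
#'
#' @return The string `"DKTGT"`.
#' @export
dktgt_motif <- function() "DKTGT"

# --- internal helpers -------------------------------------------------------

# Accept either a sequence tibble (columns id/seq[/label]) or a bare
# character vector of residue strings.
pull_seqs <- function(data) {
  if (is.character(data)) return(data)
  if (is.data.frame(data)) {
    if (!"seq" %in% names(data)) {
      abort("`data` must have a `seq` column of residue strings.")
    }
    return(data$seq)
  }
  abort("`data` must be a data frame with a `seq` column or a character vector.")
}

pull_ids <- function(data) {
  if (is.data.frame(data) && "id" %in% names(data)) return(data$id)
  if (is.character(data) && !is.null(names(data))) return(names(data))
  paste0("seq", seq_along(pull_seqs(data)))
}

# binary labels "+1"/"-1" -> integer +1/-1
label_to_y <- function(label) {
  if (is.numeric(label)) label <- ifelse(label > 0, "+1", "-1")
  y <- dplyr::case_match(as.character(label), "+1" ~ 1L, "-1" ~ -1L,
                         .default = NA_integer_)
  if (anyNA(y)) {
    bad <- unique(label[is.na(y)])
    abort(paste0("all labels must be \"+1\" or \"-1\"; found: ",
                 paste(utils::head(bad, 5), collapse = ", ")))
  }
  y
}

check_binary_data <- function(data) {
  if (!all(c("seq", "label") %in% names(data))) {
    abort("`data` must have `seq` and `label` columns.")
  }
  y <- label_to_y(data$label)
  if (all(y > 0) || all(y < 0)) {
    abort("training data must contain both a positive and a negative sequence.")
  }
  y
}
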