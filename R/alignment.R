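#' Construct a group-labelled alignment
#'
#' A labelled alignment is an ordinary tibble with one row per sequence and
#' columns `id`, `group` and `seq`, carrying the class `labeled_alignment`.
#' `group` assigns each sequence to one of the three functional categories
#' used throughout the package: `"tr"` (transferase-active), `"est"`
#' (esterase-active) and `"putative"` (function unknown). All aligned
#' sequences must have identical length; sequences are upper-cased on
#' construction.
#'
#' @param ids Character vector of unique sequence identifiers.
#' @param seqs Character vector of aligned sequences (gaps `-`), same length
#'   as `ids`.
#' @param groups Character vector of group labels, each one of `"tr"`,
#'   `"est"`, `"putative"`.
#' @return A tibble of class `labeled_alignment` with columns `id`, `group`,
#'   `seq` and attribute `n_columns`.
#' @examples
#' labeled_alignment(c("A", "B"), c("M-KL", "MAKL"), c("tr", "est"))
#' @export
labeled_alignment <- function(ids, seqs, groups) {
  ids <- as.character(ids)
  seqs <- toupper(as.character(seqs))
  groups <- as.character(groups)
  if (length(ids) != length(seqs) || length(ids) != length(groups)) {
    abort("`ids`, `seqs` and `groups` must have the same length.")
  }
  if (anyDuplicated(ids)) {
    abort(paste0("duplicate sequence id(s): ",
                 paste(unique(ids[duplicated(ids)]), collapse = ", ")))
  }
  lens <- nchar(seqs)
  if (length(unique(lens)) != 1L) {
    abort("unequal lengths: all aligned sequences must have the same number of columns.")
  }
  if (lens[1] < 1L) abort("alignment must have at least one column.")
  bad <- setdiff(unique(groups), c("tr", "est", "putative"))
  if (length(bad)) {
    abort(paste0("unknown group token(s): ", paste(bad, collapse = ", "),
                 "; accepted tokens are 'tr', 'est', 'putative'."))
  }
  if (!any(groups == "tr")) abort("alignment needs at least one 'tr' sequence.")
  if (!any(groups %in% c("est", "putative"))) {
    abort("alignment needs at least one 'est' or 'putative' sequence.")
  }
  out <- tibble::tibble(id = ids, group = groups, seq = seqs)
  attr(out, "n_columns") <- lens[1]
  class(out) <- c("labeled_alignment", class(out))
  out
}

#' Number of alignment columns
#' @param aln A `labeled_alignment`.
#' @return Integer number of columns.
#' @export
n_columns <- function(aln) {
  stopifnot(inherits(aln, "labeled_alignment"))
  nchar(aln$seq[1])
}

#' Read an aligned FASTA plus a group-label table
#'
#' The label file is tab-separated with two columns (`id`, `group`), `#`
#' comment lines allowed, no header. Every FASTA record must have exactly
#' one label; accepted group tokens are `tr`, `est` and `putative`.
#' Sequence order follows the FASTA file.
#'
#' @param fasta_path Path to an aligned protein FASTA file.
#' @param labels_path Path to the two-column TSV of group labels.
#' @return A [labeled_alignment()].
#' @export
read_alignment <- function(fasta_path, labels_path) {
  aa <- Biostrings::readAAStringSet(fasta_path)
  ids <- sub("\\s.*$", "", names(aa))
  seqs <- as.character(aa)
  lab <- read.table(labels_path, sep = "\t", header = FALSE,
                    comment.char = "#", stringsAsFactors = FALSE,
                    col.names = c("id", "group"), colClasses = "character",
                    strip.white = TRUE)
  if (anyDuplicated(lab$id)) {
    abort(paste0("duplicate id(s) in label file: ",
                 paste(unique(lab$id[duplicated(lab$id)]), collapse = ", ")))
  }
  missing <- setdiff(ids, lab$id)
  if (length(missing)) {
    abort(paste0("label missing for sequence id(s): ",
                 paste(missing, collapse = ", ")))
  }
  groups <- lab$group[match(ids, lab$id)]
  labeled_alignment(ids, seqs, groups)
}

#' Write a labelled alignment back to FASTA + label TSV
#'
#' @param aln A `labeled_alignment`.
#' @param fasta_path Output FASTA path.
#' @param labels_path Output label TSV path (optional; skipped when `NULL`).
#' @return `fasta_path`, invisibly.
#' @export
write_alignment <- function(aln, fasta_path, labels_path = NULL) {
  stopifnot(inherits(aln, "labeled_alignment"))
  set <- Biostrings::AAStringSet(setNames(aln$seq, aln$id))
  Biostrings::writeXStringSet(set, fasta_path)
  if (!is.null(labels_path)) {
    write.table(aln[, c("id", "group")], labels_path, sep = "\t",
                quote = FALSE, row.names = FALSE, col.names = FALSE)
  }
  invisible(fasta_path)
}

#' Map an alignment column to the ungapped residue position
#'
#' Both coordinates are 1-based. Returns a one-row tibble, or a zero-row
#' tibble when the sequence has a gap (or non-residue placeholder `.`) at
#' that column — the column has no residue in that sequence.
#'
#' @param aln A `labeled_alignment`.
#' @param seq_id Sequence identifier present in `aln`.
#' @param column 1-based alignment column.
#' @return Tibble with columns `seq_id`, `residue_index`, `residue`,
#'   `column`; zero rows for a gap.
#' @examples
#' aln <- labeled_alignment(c("A", "B"), c("M-KL", "MAKL"), c("tr", "est"))
#' column_to_residue(aln, "A", 3)  # residue_index 2, residue "K"
#' column_to_residue(aln, "A", 2)  # zero rows: gap
#' @export
column_to_residue <- function(aln, seq_id, column) {
  s <- aligned_chars(aln, seq_id)
  if (column < 1 || column > length(s)) {
    abort(paste0("column ", column, " out of range 1..", length(s), "."))
  }
  empty <- tibble::tibble(seq_id = character(), residue_index = integer(),
                          residue = character(), column = integer())
  if (s[column] %in% c("-", ".")) return(empty)
  idx <- sum(!(s[seq_len(column)] %in% c("-", ".")))
  tibble::tibble(seq_id = seq_id, residue_index = as.integer(idx),
                 residue = s[column], column = as.integer(column))
}

#' Map an ungapped residue position to its alignment column
#'
#' Inverse of [column_to_residue()]: for every non-gap position the
#' round trip is the identity.
#'
#' @inheritParams column_to_residue
#' @param residue_index 1-based position in the ungapped sequence.
#' @return 1-based alignment column (integer).
#' @export
residue_to_column <- function(aln, seq_id, residue_index) {
  s <- aligned_chars(aln, seq_id)
  resn <- which(!(s %in% c("-", ".")))
  if (residue_index < 1 || residue_index > length(resn)) {
    abort(paste0("residue_index ", residue_index, " out of range 1..",
                 length(resn), " for sequence '", seq_id, "'."))
  }
  as.integer(resn[residue_index])
}

# split one sequence into a character vector, validating the id
aligned_chars <- function(aln, seq_id) {
  stopifnot(inherits(aln, "labeled_alignment"))
  i <- match(seq_id, aln$id)
  if (is.na(i)) abort(paste0("unknown sequence id '", seq_id, "'."))
  strsplit(aln$seq[i], "", fixed = TRUE)[[1]]
}

# alignment as a character matrix (rows = sequences, columns = alignment
# columns); the workhorse layout for column-wise counting
alignment_matrix <- function(aln) {
  m <- do.call(rbind, strsplit(aln$seq, "", fixed = TRUE))
  rownames(m) <- aln$id
  m
}
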