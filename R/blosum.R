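# md5 of the vendored BLOSUM62 target-frequency table; guards against a
# silently edited data file
BLOSUM62_QIJ_MD5 <- "e9155c295f18fa568edadd96e8dbaa24"

# load the lower-triangle q_ab table and return the symmetric 20x20 matrix,
# normalised to unit total mass (the published 4-decimal table sums to
# 0.9987)
blosum62_target_frequencies <- function() {
  path <- system.file("extdata", "blosum62_qij.tsv", package = "gelpscan",
                      mustWork = TRUE)
  if (!identical(unname(tools::md5sum(path)), BLOSUM62_QIJ_MD5)) {
    abort("BLOSUM62 frequency table failed its checksum; reinstall the package.")
  }
  lines <- readLines(path)
  lines <- lines[!grepl("^#", lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  aa <- vapply(parts, `[`, character(1), 1L)
  stopifnot(identical(aa, AA_ALPHABET20))
  q <- matrix(0, 20, 20, dimnames = list(aa, aa))
  for (i in seq_along(parts)) {
    v <- as.numeric(parts[[i]][-1])
    q[i, seq_along(v)] <- v
    q[seq_along(v), i] <- v
  }
  q / sum(q)
}

#' BLOSUM62 pseudo-count model
#'
#' Small groups (here: four transferase-active sequences) give unstable raw
#' residue frequencies. The scan therefore regularises the per-column counts
#' with substitution-matrix pseudo-counts: observed counts are mixed with
#' counts expected under BLOSUM62, weighted by the pseudo-count mass `B`.
#' For a column with counts \eqn{N_a} and \eqn{N_{obs} = \sum_b N_b}
#' countable residues, the corrected frequency is
#' \deqn{f_a = \frac{N_a + B \sum_b (N_b / N_{obs}) P(a \mid b)}{N_{obs} + B}}
#' where \eqn{P(a \mid b) = q_{ab} / \sum_c q_{cb}} is the conditional
#' substitution probability derived from the BLOSUM62 target frequencies
#' \eqn{q_{ab}}. `B = 0` recovers the raw frequencies exactly.
#'
#' @param B Non-negative pseudo-count mass. Default 2.
#' @return An object of class `pseudo_count_model`: a list with elements
#'   `B`, `cond` (20x20 matrix, `cond[a, b]` = P(a | b), columns sum to 1),
#'   `background` (BLOSUM62 marginal frequencies) and `alphabet`.
#' @export
pseudo_count_model <- function(B = 2) {
  if (!is.numeric(B) || length(B) != 1L || is.na(B) || B < 0) {
    abort("`B` must be a single non-negative number.")
  }
  q <- blosum62_target_frequencies()
  marg <- colSums(q)
  cond <- sweep(q, 2, marg, "/")  # cond[a, b] = q_ab / sum_c q_cb
  structure(list(B = as.numeric(B), cond = cond, background = marg,
                 alphabet = AA_ALPHABET20),
            class = "pseudo_count_model")
}

#' @export
print.pseudo_count_model <- function(x, ...) {
  cat("<pseudo_count_model> BLOSUM62 conditional substitution probabilities, B =",
      format(x$B), "\n")
  invisible(x)
}
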