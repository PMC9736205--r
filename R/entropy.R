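#' Raw residue counts for one alignment column within a group
#'
#' Counts each of the 20 standard amino acids among the sequences whose
#' label is in `groups`. Gaps and ambiguity codes (B, Z, X, J, U, O, `*`)
#' contribute no counts and are tallied in `n_gap`, so
#' `sum(counts) + n_gap == n_total` always holds.
#'
#' @param aln A [labeled_alignment()].
#' @param column 1-based alignment column.
#' @param groups Non-empty subset of `c("tr", "est", "putative")`.
#' @return An object of class `column_counts`: list with `column`, `counts`
#'   (named length-20 integer vector), `n_total`, `n_gap`.
#' @export
column_counts <- function(aln, column, groups = c("tr", "est", "putative")) {
  stopifnot(inherits(aln, "labeled_alignment"))
  nc <- n_columns(aln)
  if (column < 1 || column > nc) {
    abort(paste0("column ", column, " out of range 1..", nc, "."))
  }
  groups <- match.arg(groups, several.ok = TRUE)
  chars <- substring(aln$seq[aln$group %in% groups], column, column)
  code <- match(chars, AA_ALPHABET20)
  counts <- tabulate(code, nbins = 20L)
  names(counts) <- AA_ALPHABET20
  structure(list(column = as.integer(column), counts = counts,
                 n_total = length(chars), n_gap = sum(is.na(code))),
            class = "column_counts")
}

#' Pseudo-count-corrected residue frequencies for a column
#'
#' Applies the BLOSUM62 pseudo-count mix of [pseudo_count_model()] to raw
#' column counts. With `B = 0` the raw frequencies are returned unchanged.
#' An all-gap column falls back to the BLOSUM62 background distribution when
#' `B > 0` and is an error at `B = 0`.
#'
#' @param cc A `column_counts` object (or bare named length-20 count vector).
#' @param pc A [pseudo_count_model()].
#' @param strict_nall Use the group size `n_total` (gaps included) rather
#'   than the number of countable residues in the denominator. Frequencies
#'   then sum to less than 1 on gapped columns; intended only for literal
#'   reproduction of the uncorrected frequency definition.
#' @return Named length-20 numeric vector of frequencies.
#' @export
corrected_frequencies <- function(cc, pc = pseudo_count_model(),
                                  strict_nall = FALSE) {
  if (inherits(cc, "column_counts")) {
    counts <- cc$counts
    n_total <- cc$n_total
  } else {
    counts <- cc
    n_total <- sum(counts)
  }
  stopifnot(length(counts) == 20L, all(counts >= 0))
  n_obs <- sum(counts)
  B <- pc$B
  if (n_obs == 0) {
    if (B == 0) abort("empty column: no countable residue and B = 0.")
    return(setNames(as.numeric(pc$background), AA_ALPHABET20))
  }
  pseudo <- if (B > 0) as.numeric(pc$cond %*% (counts / n_obs)) else 0
  denom <- if (strict_nall) n_total + B else n_obs + B
  setNames((counts + B * pseudo) / denom, AA_ALPHABET20)
}

#' Shannon entropy of a residue frequency vector (log10 units)
#'
#' \eqn{E = -\sum_a f_a \log_{10} f_a}, with the convention
#' \eqn{0 \cdot \log 0 = 0}. A fully conserved column has entropy 0; a
#' uniform 20-residue column has the maximum, \eqn{\log_{10} 20 \approx
#' 1.30103}.
#'
#' @param f Numeric vector of non-negative frequencies summing to at most 1.
#' @return Entropy in log10 units (single number, >= 0).
#' @examples
#' column_entropy(c(1, rep(0, 19)))      # 0
#' column_entropy(rep(1 / 20, 20))       # log10(20)
#' @export
column_entropy <- function(f) {
  if (any(f < 0)) abort("negative frequency.")
  if (sum(f) > 1 + 1e-9) abort("frequencies sum to more than 1.")
  pos <- f[f > 0]
  -sum(pos * log10(pos))
}

# 20 x n_columns count matrix for the rows of a character matrix
group_count_matrix <- function(char_matrix, rows) {
  sub <- char_matrix[rows, , drop = FALSE]
  code <- match(sub, AA_ALPHABET20)
  dim(code) <- dim(sub)
  vapply(seq_len(ncol(code)),
         function(j) tabulate(code[, j], nbins = 20L),
         integer(20L))
}

# entropy per column from a 20 x n count matrix, vectorised over columns
entropies_from_counts <- function(counts, pc, n_total, strict_nall) {
  n_obs <- colSums(counts)
  B <- pc$B
  w <- sweep(counts, 2, pmax(n_obs, 1), "/")
  pseudo <- if (B > 0) pc$cond %*% w else matrix(0, 20, ncol(counts))
  denom <- if (strict_nall) n_total + B else n_obs + B
  f <- sweep(counts + B * pseudo, 2, denom, "/")
  if (any(n_obs == 0)) {
    if (B == 0) abort("empty column: a group has no countable residue and B = 0.")
    f[, n_obs == 0] <- pc$background
  }
  -colSums(ifelse(f > 0, f * log10(f), 0))
}

#' Two-entropy profile of a labelled alignment
#'
#' For every alignment column, computes the Shannon entropy within the
#' transferase group (`E_tr`), within the background group of esterase plus
#' putative sequences (`E_other`), and their difference
#' `delta = E_other - E_tr`. Columns conserved preferentially in the
#' transferase group have large positive `delta`; a column with no
#' function/residue correlation has `delta` near zero.
#'
#' @param aln A [labeled_alignment()] with at least one `tr` and one
#'   `est`/`putative` sequence.
#' @param pc A [pseudo_count_model()]; default uses `B = 2`.
#' @param strict_nall See [corrected_frequencies()].
#' @return Tibble with one row per column: `column`, `E_tr`, `E_other`,
#'   `delta`, `n_gap_tr`, `n_gap_other`.
#' @export
entropy_profile <- function(aln, pc = pseudo_count_model(),
                            strict_nall = FALSE) {
  stopifnot(inherits(aln, "labeled_alignment"))
  m <- alignment_matrix(aln)
  tr_rows <- aln$group == "tr"
  other_rows <- aln$group %in% c("est", "putative")
  if (!any(tr_rows)) abort("empty group: no 'tr' sequences.")
  if (!any(other_rows)) abort("empty group: no 'est' or 'putative' sequences.")
  c_tr <- group_count_matrix(m, tr_rows)
  c_other <- group_count_matrix(m, other_rows)
  e_tr <- entropies_from_counts(c_tr, pc, sum(tr_rows), strict_nall)
  e_other <- entropies_from_counts(c_other, pc, sum(other_rows), strict_nall)
  tibble::tibble(
    column = seq_len(ncol(m)),
    E_tr = e_tr,
    E_other = e_other,
    delta = e_other - e_tr,
    n_gap_tr = sum(tr_rows) - colSums(c_tr),
    n_gap_other = sum(other_rows) - colSums(c_other)
  )
}

#' Rank alignment columns by entropy difference
#'
#' Selects the `k` columns with the largest `delta` (background entropy
#' minus transferase-group entropy). Ties are broken deterministically by
#' the smaller column index. Columns listed in `exclude_columns` (for
#' example a declared signal-peptide region) are skipped before ranking.
#'
#' A residue can only be conserved in *all* transferase sequences if every
#' transferase sequence carries a residue at the column, so by default any
#' column with a gap in the transferase group is ineligible (`max_gap_tr =
#' 0`); without this, heavily gapped columns mimic conservation because the
#' few observed residues happen to agree. An optional ceiling `max_E_tr`
#' additionally requires the transferase group itself to be conserved.
#'
#' @param profile Tibble from [entropy_profile()].
#' @param k Number of candidates to keep (default 10).
#' @param exclude_columns Integer vector of columns to skip, or `NULL`.
#' @param max_gap_tr Maximum number of transferase-group gaps allowed at a
#'   candidate column (default 0); ignored when the profile carries no
#'   `n_gap_tr` column.
#' @param max_E_tr Optional upper bound on `E_tr`; `NULL` (default) applies
#'   no per-group threshold.
#' @return Tibble `rank`, `column`, `delta`, `E_tr`, `E_other`; `rank` is
#'   1-based, increasing as `delta` decreases.
#' @export
rank_candidates <- function(profile, k = 10, exclude_columns = NULL,
                            max_gap_tr = 0, max_E_tr = NULL) {
  stopifnot(is.data.frame(profile), k >= 1)
  eligible <- profile
  if (!is.null(exclude_columns)) {
    eligible <- dplyr::filter(eligible, !.data$column %in% exclude_columns)
  }
  if (!is.null(max_gap_tr) && "n_gap_tr" %in% names(eligible)) {
    eligible <- dplyr::filter(eligible, .data$n_gap_tr <= max_gap_tr)
  }
  if (!is.null(max_E_tr)) {
    eligible <- dplyr::filter(eligible, .data$E_tr <= max_E_tr)
  }
  if (k > nrow(eligible)) {
    warn(paste0("only ", nrow(eligible), " eligible columns; returning all."))
    k <- nrow(eligible)
  }
  eligible |>
    dplyr::arrange(dplyr::desc(.data$delta), .data$column) |>
    dplyr::slice_head(n = k) |>
    dplyr::mutate(rank = dplyr::row_number(), .before = 1) |>
    dplyr::select("rank", "column", "delta", "E_tr", "E_other")
}

# set of countable residues observed in a label group at one column
group_residue_set <- function(aln, column, groups) {
  chars <- substring(aln$seq[aln$group %in% groups], column, column)
  sort(unique(chars[chars %in% AA_ALPHABET20]))
}

#' Flag candidate columns whose transferase residues are absent from
#' esterase sequences
#'
#' For each candidate column, `tr_residues` is the set of residues observed
#' in the transferase group and `absent_from_est` is `TRUE` when no
#' esterase-labelled sequence carries any of those residues at the column.
#' Gaps in esterase sequences never count as presence.
#'
#' @param aln A [labeled_alignment()].
#' @param candidates Tibble from [rank_candidates()] (any tibble with a
#'   `column` column works).
#' @return `candidates` with `tr_residues` (comma-joined string) and
#'   `absent_from_est` (logical) appended.
#' @export
est_absence_filter <- function(aln, candidates) {
  stopifnot(inherits(aln, "labeled_alignment"), is.data.frame(candidates))
  res <- purrr::map(candidates$column, function(col) {
    tr_set <- group_residue_set(aln, col, "tr")
    est_set <- group_residue_set(aln, col, "est")
    tibble::tibble(tr_residues = paste(tr_set, collapse = ","),
                   absent_from_est = !any(est_set %in% tr_set))
  })
  dplyr::bind_cols(candidates, purrr::list_rbind(res))
}

#' Map candidate columns onto reference-sequence residue numbers
#'
#' @param aln A [labeled_alignment()].
#' @param candidates Tibble with a `column` column.
#' @param reference_ids Sequence ids to map each candidate column onto.
#' @return Long tibble: `column`, `seq_id`, `residue_index`, `residue`;
#'   columns falling on a gap of a reference yield `NA` for that reference.
#' @export
candidate_reference_map <- function(aln, candidates, reference_ids) {
  grid <- tidyr::expand_grid(column = unique(candidates$column),
                             seq_id = reference_ids)
  purrr::pmap(grid, function(column, seq_id) {
    hit <- column_to_residue(aln, seq_id, column)
    if (nrow(hit) == 0) {
      tibble::tibble(column = as.integer(column), seq_id = seq_id,
                     residue_index = NA_integer_, residue = NA_character_)
    } else {
      hit[, c("column", "seq_id", "residue_index", "residue")]
    }
  }) |> purrr::list_rbind()
}

#' Classify sequences by their residues at two candidate columns
#'
#' Each sequence is assigned `both`, `pos1_only`, `pos2_only` or `neither`
#' according to whether its residue at each candidate column belongs to the
#' corresponding accepted residue set. A gap counts as absence.
#'
#' @param aln A [labeled_alignment()].
#' @param col1,col2 1-based candidate alignment columns.
#' @param res1,res2 Non-empty character vectors of accepted residues (e.g.
#'   `c("N", "R")` and `"D"`).
#' @return Tibble `seq_id`, `group`, `at_col1`, `at_col2`, `status`.
#' @export
classify_sequences <- function(aln, col1, res1, col2, res2) {
  stopifnot(inherits(aln, "labeled_alignment"),
            length(res1) >= 1, length(res2) >= 1)
  nc <- n_columns(aln)
  if (col1 < 1 || col1 > nc || col2 < 1 || col2 > nc) {
    abort("candidate column out of range.")
  }
  c1 <- substring(aln$seq, col1, col1)
  c2 <- substring(aln$seq, col2, col2)
  has1 <- c1 %in% toupper(res1)
  has2 <- c2 %in% toupper(res2)
  tibble::tibble(
    seq_id = aln$id,
    group = aln$group,
    at_col1 = c1,
    at_col2 = c2,
    status = dplyr::case_when(
      has1 & has2 ~ "both",
      has1 ~ "pos1_only",
      has2 ~ "pos2_only",
      .default = "neither"
    )
  )
}
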