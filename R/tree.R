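#' Annotate phylogenetic tree tips with candidate-residue status
#'
#' Matches the tip labels of a Newick tree against a sequence-status table
#' (from [classify_sequences()]) and writes (i) the same topology with the
#' status attached to each tip as an NHX-style comment
#' (`tip[&&NHX:status=both]`) and (ii) a plain tip-to-status TSV. Tips with
#' no matching sequence id are labelled `"unknown"` and reported with a
#' warning. The topology is never altered.
#'
#' @param newick_path Path to a Newick file whose tip names match sequence
#'   ids exactly.
#' @param statuses Tibble with columns `seq_id` and `status`.
#' @param out_newick,out_tsv Output paths; `NULL` skips writing that file.
#' @return Invisibly, a list with `tree` (the `phylo` object), `tip_status`
#'   (tibble `tip`, `status`) and `n_unknown`.
#' @export
annotate_tree <- function(newick_path, statuses, out_newick = NULL,
                          out_tsv = NULL) {
  tree <- tryCatch(ape::read.tree(newick_path),
                   error = function(e) abort(paste0("unparsable Newick: ",
                                                    conditionMessage(e))))
  if (is.null(tree) || is.null(tree$tip.label)) abort("unparsable Newick file.")
  tips <- tree$tip.label
  status <- statuses$status[match(tips, statuses$seq_id)]
  unknown <- tips[is.na(status)]
  if (length(unknown) == length(tips)) {
    abort("no tree tip matches any sequence id in `statuses`.")
  }
  if (length(unknown)) {
    warn(paste0(length(unknown), " tip(s) without a status, labelled 'unknown': ",
                paste(unknown, collapse = ", ")))
    status[is.na(status)] <- "unknown"
  }
  tip_status <- tibble::tibble(tip = tips, status = status)

  if (!is.null(out_newick)) {
    # write with collision-proof placeholder labels, then substitute the
    # original label plus its NHX comment (labels may contain regex
    # metacharacters, so plain fixed replacement on unique tokens)
    ph_tree <- tree
    ph <- sprintf("GELPSCANTIP%06dX", seq_along(tips))
    ph_tree$tip.label <- ph
    nwk <- ape::write.tree(ph_tree)
    for (i in seq_along(tips)) {
      nwk <- sub(ph[i],
                 paste0(tips[i], "[&&NHX:status=", status[i], "]"),
                 nwk, fixed = TRUE)
    }
    writeLines(nwk, out_newick)
  }
  if (!is.null(out_tsv)) {
    write.table(tip_status, out_tsv, sep = "\t", quote = FALSE,
                row.names = FALSE)
  }
  invisible(list(tree = tree, tip_status = tip_status,
                 n_unknown = length(unknown)))
}

#' Strip NHX comments from an annotated Newick file
#'
#' Utility to recover a plain Newick string (e.g. to verify that annotation
#' preserved the topology).
#'
#' @param newick_path Path to an annotated Newick file.
#' @return A `phylo` object parsed from the comment-free string.
#' @export
read_annotated_tree <- function(newick_path) {
  nwk <- paste(readLines(newick_path), collapse = "")
  ape::read.tree(text = gsub("\\[[^]]*\\]", "", nwk))
}
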