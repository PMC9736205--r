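# evaluate one pipeline stage, prefixing any error with the stage name
run_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    abort(paste0("stage '", stage, "': ", conditionMessage(e)))
  })
}

# remove files already written when a later stage fails
with_cleanup <- function(paths_env, expr) {
  tryCatch(expr, error = function(e) {
    existing <- paths_env$written[file.exists(paths_env$written)]
    unlink(existing)
    rlang::cnd_signal(e)
  })
}

write_run_manifest <- function(out_dir, subcommand, config, inputs,
                               seed = NULL) {
  inputs <- inputs[file.exists(inputs)]
  manifest <- list(
    subcommand = subcommand,
    tool = "gelpscan",
    version = as.character(utils::packageVersion("gelpscan")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seed = seed,
    config = config,
    inputs = lapply(inputs, function(f)
      list(file = f, md5 = unname(tools::md5sum(f))))
  )
  path <- file.path(out_dir, "run_manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, null = "null")
  path
}

write_tsv_file <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the entropy scan end to end
#'
#' Composition of [read_alignment()], [entropy_profile()],
#' [rank_candidates()], [est_absence_filter()],
#' [candidate_reference_map()] and [classify_sequences()] (plus
#' [annotate_tree()] when a tree is supplied), writing one TSV per stage
#' and a JSON run manifest into `out_dir`. Errors carry the failing stage's
#' name and remove partial outputs.
#'
#' @param fasta_path,labels_path Alignment inputs; see [read_alignment()].
#' @param out_dir Output directory (created if needed).
#' @param pseudo_count Pseudo-count mass `B` (default 2).
#' @param top_k Number of ranked candidates (default 10).
#' @param exclude_columns Columns excluded from ranking, or `NULL`.
#' @param strict_nall See [corrected_frequencies()].
#' @param reference_ids Sequences onto which candidate columns are mapped;
#'   default: the first `tr`-labelled sequence.
#' @param classify_columns Length-2 integer vector of columns for the
#'   sequence-status classification; default: the two top-ranked candidates
#'   passing the esterase-absence filter (falling back to the top two
#'   overall when fewer than two pass).
#' @param newick_path Optional Newick tree to annotate with statuses.
#' @return Invisibly, a list with `profile`, `candidates`, `statuses`,
#'   `reference_map` and `paths`.
#' @export
run_entropy_pipeline <- function(fasta_path, labels_path, out_dir,
                                 pseudo_count = 2, top_k = 10,
                                 exclude_columns = NULL, strict_nall = FALSE,
                                 reference_ids = NULL,
                                 classify_columns = NULL,
                                 newick_path = NULL) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  env <- new.env()
  env$written <- character()
  note <- function(p) { env$written <- c(env$written, p); p }
  with_cleanup(env, {
    aln <- run_stage("read_alignment",
                     read_alignment(fasta_path, labels_path))
    pc <- pseudo_count_model(pseudo_count)
    profile <- run_stage("entropy_profile",
                         entropy_profile(aln, pc, strict_nall = strict_nall))
    note(write_tsv_file(profile, file.path(out_dir, "profile.tsv")))
    candidates <- run_stage("rank_candidates",
                            rank_candidates(profile, k = top_k,
                                            exclude_columns = exclude_columns))
    candidates <- run_stage("est_absence_filter",
                            est_absence_filter(aln, candidates))
    if (is.null(reference_ids)) reference_ids <- aln$id[aln$group == "tr"][1]
    refmap <- run_stage("candidate_reference_map",
                        candidate_reference_map(aln, candidates,
                                                reference_ids))
    candidates_out <- candidates |>
      dplyr::left_join(refmap, by = "column",
                       relationship = "many-to-many")
    note(write_tsv_file(candidates_out, file.path(out_dir, "candidates.tsv")))

    if (is.null(classify_columns)) {
      passing <- candidates[candidates$absent_from_est, ]
      pick <- if (nrow(passing) >= 2) passing else candidates
      classify_columns <- head(pick$column, 2)
    }
    statuses <- NULL
    if (length(classify_columns) == 2) {
      sets <- purrr::map(classify_columns, function(col) {
        i <- match(col, candidates$column)
        if (!is.na(i)) strsplit(candidates$tr_residues[i], ",")[[1]]
        else group_residue_set(aln, col, "tr")
      })
      statuses <- run_stage("classify_sequences",
                            classify_sequences(aln, classify_columns[1],
                                               sets[[1]], classify_columns[2],
                                               sets[[2]]))
      note(write_tsv_file(statuses, file.path(out_dir, "status.tsv")))
      if (!is.null(newick_path)) {
        run_stage("annotate_tree",
                  annotate_tree(newick_path, statuses,
                                out_newick = note(file.path(out_dir,
                                                            "annotated.nwk")),
                                out_tsv = note(file.path(out_dir,
                                                         "tip_status.tsv"))))
      }
    }
    manifest <- write_run_manifest(
      out_dir, "entropy",
      config = list(pseudo_count = pseudo_count, top_k = top_k,
                    exclude_columns = exclude_columns,
                    strict_nall = strict_nall,
                    reference_ids = reference_ids,
                    classify_columns = classify_columns),
      inputs = c(fasta_path, labels_path, newick_path %||% character()))
    invisible(list(profile = profile, candidates = candidates_out,
                   statuses = statuses, reference_map = refmap,
                   paths = c(env$written, manifest)))
  })
}

#' Run the pose-counting and Dunnett stage end to end
#'
#' Reads a manifest of receptor structure models and docked pose files (one
#' row per variant and model; columns `variant_id`, `model_rank`,
#' `structure_file`, `poses1_file`, `poses2_file`), counts reasonable
#' models per variant with [count_reasonable()], and compares every
#' treatment variant against the control with [dunnett_many_to_one()].
#' Writes `audit.tsv` (every pose pair with both distances), `counts.tsv`,
#' `dunnett.tsv` and a JSON run manifest recording cutoffs and selectors.
#'
#' @param manifest Path to the manifest TSV, or an equivalent data frame.
#' @param out_dir Output directory (created if needed).
#' @param control Variant id of the control (default `"native"`).
#' @param criteria A [criteria_spec()].
#' @param alpha Significance level (default 0.05).
#' @param seed Seed for the Dunnett Monte Carlo (required).
#' @param mc_draws Monte-Carlo draws (default 1e5).
#' @param triad Catalytic-triad residue numbers passed to
#'   [read_structure()].
#' @return Invisibly, a list with `counts` (tibble), `summary` (per-variant
#'   mean/sd), `dunnett` (`gelp_dunnett`), `audit` and `paths`.
#' @export
run_pose_pipeline <- function(manifest, out_dir, control = "native",
                              criteria = criteria_spec(), alpha = 0.05,
                              seed, mc_draws = 1e5,
                              triad = criteria$triad) {
  if (missing(seed)) abort("`seed` is required.")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  env <- new.env()
  env$written <- character()
  note <- function(p) { env$written <- c(env$written, p); p }
  with_cleanup(env, {
    man <- run_stage("read_manifest", {
      m <- if (is.data.frame(manifest)) manifest
      else read.table(manifest, sep = "\t", header = TRUE,
                      stringsAsFactors = FALSE)
      need <- c("variant_id", "model_rank", "structure_file", "poses1_file",
                "poses2_file")
      if (!all(need %in% names(m))) {
        abort(paste0("manifest must have columns: ",
                     paste(need, collapse = ", ")))
      }
      m
    })
    variants <- unique(man$variant_id)
    if (!control %in% variants) {
      abort(paste0("control variant '", control, "' absent from manifest."))
    }
    if (length(variants) < 2) abort("no treatment variants.")

    counts <- purrr::map(variants, function(vid) {
      rows <- man[man$variant_id == vid, ]
      models <- purrr::pmap(rows, function(variant_id, model_rank,
                                           structure_file, poses1_file,
                                           poses2_file, ...) {
        run_stage("read_structure", {
          s <- read_structure(structure_file, triad = triad,
                              variant_id = variant_id,
                              model_rank = as.integer(model_rank))
          list(structure = s,
               poses1 = run_stage("read_poses",
                                  read_poses(poses1_file, "substrate1")),
               poses2 = run_stage("read_poses",
                                  read_poses(poses2_file, "substrate2")))
        })
      })
      run_stage("count_reasonable",
                count_reasonable(vid, models, criteria))
    })
    names(counts) <- variants

    audit <- purrr::list_rbind(purrr::map(counts, function(rc) {
      dplyr::mutate(rc$audit, variant_id = rc$variant_id, .before = 1)
    }))
    per_model <- purrr::list_rbind(purrr::map(counts, tidy))
    summary <- purrr::list_rbind(purrr::map(counts, glance))
    note(write_tsv_file(audit, file.path(out_dir, "audit.tsv")))
    note(write_tsv_file(per_model, file.path(out_dir, "counts.tsv")))

    dun <- run_stage("dunnett", {
      trts <- purrr::map(setdiff(variants, control),
                         function(v) counts[[v]]$counts)
      names(trts) <- setdiff(variants, control)
      dunnett_many_to_one(counts[[control]]$counts, trts, alpha = alpha,
                          seed = seed, mc_draws = mc_draws)
    })
    note(write_tsv_file(tidy(dun), file.path(out_dir, "dunnett.tsv")))
    manifest_path <- write_run_manifest(
      out_dir, "posecount",
      config = list(control = control, alpha = alpha, mc_draws = mc_draws,
                    cutoff1 = criteria$stage1$cutoff,
                    cutoff2 = criteria$stage2$cutoff,
                    stage1_ligand = criteria$stage1$ligand,
                    stage1_receptor = criteria$stage1$receptor,
                    stage2_ligand = criteria$stage2$ligand,
                    stage2_receptor = criteria$stage2$receptor,
                    triad = as.list(triad)),
      inputs = if (is.character(manifest)) manifest else character(),
      seed = seed)
    invisible(list(counts = per_model, summary = summary, dunnett = dun,
                   audit = audit, paths = c(env$written, manifest_path)))
  })
}
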