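#' Specification for a simulated group-labelled alignment
#'
#' The generator emulates the study corpus: a small transferase group, a
#' handful of esterase sequences, a large BLAST-collected putative
#' background, columns drawn from the BLOSUM62 marginal residue
#' distribution (so background entropies spread realistically below the
#' log10(20) ceiling), an N-terminal stretch of elevated transferase-group
#' variability mimicking a signal peptide, gaps, and a set of planted
#' columns conserved only in the transferase group.
#'
#' @param n_tr,n_est,n_putative Group sizes (defaults 4, 6, 100).
#' @param n_columns Alignment length (default 500).
#' @param planted List of planted columns; each element a list with
#'   `column`, `residues` (character vector drawn from uniformly in the
#'   transferase group), `conservation` (probability a transferase sequence
#'   carries a planted residue, default 1) and `est_exclusion` (esterase
#'   sequences never carry a planted residue, default `TRUE`).
#' @param gap_prob Per-cell gap probability outside planted transferase
#'   cells (default 0.2).
#' @param signal_region Number of leading columns where transferase
#'   sequences are drawn uniformly over the 20 residues (default 25).
#' @param seed Integer seed (required).
#' @return A list of class `msa_sim_spec`.
#' @export
msa_sim_spec <- function(n_tr = 4, n_est = 6, n_putative = 100,
                         n_columns = 500,
                         planted = list(
                           list(column = 208, residues = c("N", "R"),
                                conservation = 1, est_exclusion = TRUE),
                           list(column = 484, residues = "D",
                                conservation = 1, est_exclusion = TRUE)),
                         gap_prob = 0.2, signal_region = 25, seed) {
  if (missing(seed)) abort("`seed` is required.")
  cols <- vapply(planted, function(p) as.integer(p$column), 1L)
  if (anyDuplicated(cols)) abort("planted columns must be distinct.")
  if (any(cols < 1 | cols > n_columns)) abort("planted column out of range.")
  probs <- vapply(planted, function(p) p$conservation %||% 1, 1)
  if (any(probs < 0 | probs > 1) || gap_prob < 0 || gap_prob > 1) {
    abort("probabilities must lie in [0, 1].")
  }
  structure(list(n_tr = n_tr, n_est = n_est, n_putative = n_putative,
                 n_columns = as.integer(n_columns), planted = planted,
                 gap_prob = gap_prob, signal_region = as.integer(signal_region),
                 seed = as.integer(seed)),
            class = "msa_sim_spec")
}

#' Simulate a group-labelled alignment with planted transferase columns
#'
#' Deterministic for a fixed seed. Planted columns carry residues from the
#' planted set in transferase sequences (never gapped there); esterase
#' sequences never carry a planted residue when `est_exclusion` is set;
#' putative sequences are unconstrained, so a planted residue can re-occur
#' in the background, as it does in real families.
#'
#' @param spec An [msa_sim_spec()].
#' @return List with `alignment` (a [labeled_alignment()]) and `truth`
#'   (tibble `column`, `residues`, `conservation`, `est_exclusion`).
#' @export
simulate_msa <- function(spec) {
  stopifnot(inherits(spec, "msa_sim_spec"))
  bg <- pseudo_count_model(0)$background
  n <- spec$n_tr + spec$n_est + spec$n_putative
  groups <- rep(c("tr", "est", "putative"),
                c(spec$n_tr, spec$n_est, spec$n_putative))
  ids <- paste0(groups, "_", c(seq_len(spec$n_tr), seq_len(spec$n_est),
                               seq_len(spec$n_putative)))
  m <- with_preserved_seed(spec$seed, {
    m <- matrix(sample(AA_ALPHABET20, n * spec$n_columns, replace = TRUE,
                       prob = bg),
                nrow = n, ncol = spec$n_columns)
    gap <- matrix(runif(n * spec$n_columns) < spec$gap_prob,
                  nrow = n, ncol = spec$n_columns)
    tr_rows <- which(groups == "tr")
    est_rows <- which(groups == "est")
    if (spec$signal_region > 0) {
      sig <- seq_len(min(spec$signal_region, spec$n_columns))
      m[tr_rows, sig] <- sample(AA_ALPHABET20,
                                length(tr_rows) * length(sig), replace = TRUE)
    }
    for (p in spec$planted) {
      col <- p$column
      res <- toupper(p$residues)
      keep <- runif(length(tr_rows)) <= (p$conservation %||% 1)
      draw <- sample(res, length(tr_rows), replace = TRUE)
      m[tr_rows[keep], col] <- draw[keep]
      gap[tr_rows[keep], col] <- FALSE
      if (isTRUE(p$est_exclusion %||% TRUE)) {
        pool <- setdiff(AA_ALPHABET20, res)
        m[est_rows, col] <- sample(pool, length(est_rows), replace = TRUE,
                                   prob = bg[pool] / sum(bg[pool]))
      }
    }
    m[gap] <- "-"
    m
  })
  truth <- purrr::map(spec$planted, function(p) {
    tibble::tibble(column = as.integer(p$column),
                   residues = paste(toupper(p$residues), collapse = ","),
                   conservation = p$conservation %||% 1,
                   est_exclusion = isTRUE(p$est_exclusion %||% TRUE))
  }) |> purrr::list_rbind()
  list(alignment = labeled_alignment(ids, apply(m, 1, paste, collapse = ""),
                                     groups),
       truth = truth)
}

#' Specification for simulated receptor models and docked pose sets
#'
#' Emulates the docking layout: a handful of predicted structure models per
#' protein variant, up to 20 substrate-1 and 20 substrate-2 poses per model.
#' Each pose is assigned a Bernoulli truth label (accept/reject) and its
#' criterion atom is placed inside the acceptance shell
#' (distance ~ Uniform(1, cutoff)) or outside it
#' (Uniform(cutoff + guard, cutoff + 30)); the guard gap keeps truth labels
#' robust to floating point.
#'
#' @param n_models Structure models per variant (default 5).
#' @param n_pose1,n_pose2 Poses per substrate per model (default 20).
#' @param accept_frac1,accept_frac2 Per-stage acceptance probabilities.
#' @param cutoff1,cutoff2 Stage cutoffs in Angstrom (mirror the
#'   [criteria_spec()] used for filtering).
#' @param guard Guard gap around the cutoffs in Angstrom (default 2).
#' @param variant_id Variant label.
#' @param seed Integer seed (required).
#' @return A list of class `pose_sim_spec`.
#' @export
pose_sim_spec <- function(n_models = 5, n_pose1 = 20, n_pose2 = 20,
                          accept_frac1 = 0.5, accept_frac2 = 0.5,
                          cutoff1 = 5, cutoff2 = 5, guard = 2,
                          variant_id = "native", seed) {
  if (missing(seed)) abort("`seed` is required.")
  stopifnot(accept_frac1 >= 0, accept_frac1 <= 1,
            accept_frac2 >= 0, accept_frac2 <= 1,
            cutoff1 > 0, cutoff2 > 0, guard > 0)
  structure(list(n_models = n_models, n_pose1 = n_pose1, n_pose2 = n_pose2,
                 accept_frac1 = accept_frac1, accept_frac2 = accept_frac2,
                 cutoff1 = cutoff1, cutoff2 = cutoff2, guard = guard,
                 variant_id = variant_id, seed = as.integer(seed)),
            class = "pose_sim_spec")
}

# idealised triad residue templates (local coordinates, heavy atoms only)
triad_template <- function() {
  res <- function(name, number, origin, extra) {
    base <- rbind(N = c(-1.2, 0.8, 0), CA = c(0, 0, 0), C = c(1.3, 0.6, 0),
                  O = c(1.5, 1.8, 0.2))
    at <- rbind(base, extra)
    tibble::tibble(atom_name = rownames(at), residue_name = name,
                   residue_number = number, chain = "A", element =
                     substr(rownames(at), 1, 1),
                   x = at[, 1] + origin[1], y = at[, 2] + origin[2],
                   z = at[, 3] + origin[3])
  }
  dplyr::bind_rows(
    res("SER", 40L, c(0, 0, 0), rbind(CB = c(-0.5, -1.2, 0.9),
                                      OG = c(-0.2, -2.4, 1.6))),
    res("ASP", 318L, c(5.5, 0, 1), rbind(CB = c(-0.4, -1.3, 0.8),
                                         CG = c(0.3, -2.5, 1.2),
                                         OD1 = c(1.5, -2.5, 1.4),
                                         OD2 = c(-0.4, -3.5, 1.3))),
    res("HIS", 321L, c(2.5, 4.5, -0.5), rbind(CB = c(-0.5, -1.3, 0.8),
                                              CG = c(0.2, -2.5, 1.1),
                                              ND1 = c(1.5, -2.7, 1.1),
                                              CD2 = c(-0.4, -3.6, 1.4),
                                              CE1 = c(1.5, -4.0, 1.3),
                                              NE2 = c(0.4, -4.6, 1.5)))
  )
}

random_unit_vector <- function() {
  v <- rnorm(3)
  v / sqrt(sum(v^2))
}

# place a point whose minimum distance to `anchor` atoms is exactly `d`:
# anchor at the atom with maximal projection onto a random direction u and
# step d along u. For any other atom b, ||(a* - b) + d u|| >= (a* - b).u + d
# >= d, so a* is provably the nearest atom.
place_at_min_distance <- function(anchor, d) {
  pts <- as.matrix(anchor[, c("x", "y", "z")])
  u <- random_unit_vector()
  proj <- pts %*% u
  a_star <- pts[which.max(proj), ]
  a_star + d * u
}

# ligand pose: criterion atom at `pos` plus a short carbon tail
ligand_pose <- function(pose_rank, crit_name, crit_element, pos) {
  tail1 <- pos + c(1.8, 0, 0)
  tail2 <- pos + c(2.7, 1.1, 0.4)
  tibble::tibble(pose_rank = as.integer(pose_rank),
                 atom_name = c(crit_name, "C1", "C2"),
                 residue_name = "LIG",
                 element = c(crit_element, "C", "C"),
                 x = c(pos[1], tail1[1], tail2[1]),
                 y = c(pos[2], tail1[2], tail2[2]),
                 z = c(pos[3], tail1[3], tail2[3]))
}

#' Simulate receptor structure models and docked pose sets
#'
#' Deterministic for a fixed seed. The returned acceptance truth labels are
#' exactly recoverable by [stage1_accept()]/[stage2_accept()] with a
#' matching [criteria_spec()], because criterion atoms are placed inside or
#' outside disjoint distance shells separated by the guard gap.
#'
#' @param spec A [pose_sim_spec()].
#' @return List with `models` (ready for [count_reasonable()]: per model a
#'   list of `structure`, `poses1`, `poses2`), `truth` (tibble
#'   `model_rank`, `substrate`, `pose_rank`, `accept`, `target_distance`)
#'   and `spec`.
#' @export
simulate_poses <- function(spec) {
  stopifnot(inherits(spec, "pose_sim_spec"))
  template <- triad_template()
  with_preserved_seed(spec$seed, {
    out <- purrr::map(seq_len(spec$n_models), function(mr) {
      atoms <- template
      # filler residues away from the active site
      filler <- purrr::map(1:4, function(i) {
        ctr <- random_unit_vector() * runif(1, 12, 30)
        tibble::tibble(atom_name = c("N", "CA", "C", "O"),
                       residue_name = "GLY",
                       residue_number = 100L + i, chain = "A",
                       element = c("N", "C", "C", "O"),
                       x = ctr[1] + c(-1.2, 0, 1.3, 1.5),
                       y = ctr[2] + c(0.8, 0, 0.6, 1.8),
                       z = ctr[3] + c(0, 0, 0, 0.2))
      }) |> purrr::list_rbind()
      # small per-model jitter emulates conformational spread across models
      atoms <- dplyr::bind_rows(atoms, filler)
      jit <- matrix(rnorm(3 * nrow(atoms), sd = 0.05), ncol = 3)
      atoms$x <- atoms$x + jit[, 1]
      atoms$y <- atoms$y + jit[, 2]
      atoms$z <- atoms$z + jit[, 3]
      s <- structure_model(atoms, variant_id = spec$variant_id,
                           model_rank = mr)
      ce1 <- s[s$residue_number == 321 & s$atom_name == "CE1", ]
      triad_heavy <- triad_atoms(s)

      sample_shell <- function(accept, cutoff) {
        if (accept) runif(1, 1, cutoff)
        else runif(1, cutoff + spec$guard, cutoff + 30)
      }
      acc1 <- runif(spec$n_pose1) < spec$accept_frac1
      d1 <- vapply(acc1, sample_shell, 0, cutoff = spec$cutoff1)
      poses1 <- purrr::map(seq_len(spec$n_pose1), function(i) {
        pos <- c(ce1$x, ce1$y, ce1$z) + d1[i] * random_unit_vector()
        ligand_pose(i, "S1", "S", pos)
      }) |> purrr::list_rbind()

      acc2 <- runif(spec$n_pose2) < spec$accept_frac2
      d2 <- vapply(acc2, sample_shell, 0, cutoff = spec$cutoff2)
      poses2 <- purrr::map(seq_len(spec$n_pose2), function(i) {
        pos <- place_at_min_distance(triad_heavy, d2[i])
        ligand_pose(i, "O1", "O", pos)
      }) |> purrr::list_rbind()

      truth <- dplyr::bind_rows(
        tibble::tibble(model_rank = mr, substrate = "substrate1",
                       pose_rank = seq_len(spec$n_pose1), accept = acc1,
                       target_distance = d1),
        tibble::tibble(model_rank = mr, substrate = "substrate2",
                       pose_rank = seq_len(spec$n_pose2), accept = acc2,
                       target_distance = d2))
      list(model = list(structure = s, poses1 = poses1, poses2 = poses2),
           truth = truth)
    })
    list(models = purrr::map(out, "model"),
         truth = purrr::list_rbind(purrr::map(out, "truth")),
         spec = spec)
  })
}

#' Write a simulated alignment to FASTA + labels (+ truth JSON)
#'
#' @param sim Result of [simulate_msa()].
#' @param dir Output directory (created if needed).
#' @return Tibble of written paths, invisibly.
#' @export
write_simulated_msa <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fasta <- file.path(dir, "alignment.fasta")
  labels <- file.path(dir, "labels.tsv")
  truth <- file.path(dir, "truth.json")
  write_alignment(sim$alignment, fasta, labels)
  jsonlite::write_json(sim$truth, truth, dataframe = "rows")
  invisible(tibble::tibble(file = c(fasta, labels, truth)))
}

#' Write simulated structures and poses as PDB/PDBQT files plus a manifest
#'
#' The manifest TSV (columns `variant_id`, `model_rank`, `structure_file`,
#' `poses1_file`, `poses2_file`) is the input format of
#' [run_pose_pipeline()].
#'
#' @param sims A single [simulate_poses()] result or a list of them (one
#'   per variant).
#' @param dir Output directory (created if needed).
#' @return The manifest tibble, invisibly; also written to
#'   `dir/manifest.tsv` and the pose truth to `dir/truth.json`.
#' @export
write_simulated_poses <- function(sims, dir) {
  if (!is.null(sims$models)) sims <- list(sims)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rows <- purrr::map(sims, function(sim) {
    vid <- sim$spec$variant_id
    purrr::imap(sim$models, function(mod, i) {
      sf <- file.path(dir, sprintf("%s_model%d.pdb", vid, i))
      p1 <- file.path(dir, sprintf("%s_model%d_substrate1.pdbqt", vid, i))
      p2 <- file.path(dir, sprintf("%s_model%d_substrate2.pdbqt", vid, i))
      write_structure(mod$structure, sf)
      write_poses(mod$poses1, p1)
      write_poses(mod$poses2, p2)
      tibble::tibble(variant_id = vid, model_rank = i, structure_file = sf,
                     poses1_file = p1, poses2_file = p2)
    }) |> purrr::list_rbind()
  }) |> purrr::list_rbind()
  write.table(rows, file.path(dir, "manifest.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  truth <- purrr::list_rbind(purrr::map(sims, function(sim) {
    dplyr::mutate(sim$truth, variant_id = sim$spec$variant_id, .before = 1)
  }))
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       dataframe = "rows")
  invisible(rows)
}
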