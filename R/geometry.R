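#' Geometric acceptance criteria for docked substrate poses
#'
#' The two-stage filter mirrors the docking workflow: stage 1 accepts a
#' substrate-1 (acyl-CoA) pose when its thioester sulfur lies within
#' `cutoff1` of the C-2 carbon of the catalytic histidine imidazole (PDB
#' atom name `CE1`; a broader `CD2|CE1` fallback can be supplied); stage 2
#' accepts a substrate-2 (alcohol) pose when its reactive hydroxyl oxygen
#' lies within `cutoff2` of any heavy atom of the catalytic triad. A
#' structure-model/pose-pair combination passing both stages is a
#' "reasonable model".
#'
#' Selectors are lists with any of the fields `element`, `atom_name`
#' (regular expression on the PDB atom name), `residue_number` (integer
#' vector) and `heavy` (`TRUE` drops hydrogens); conditions are combined
#' with AND.
#'
#' @param cutoff1,cutoff2 Stage distance cutoffs in Angstrom (must be > 0;
#'   acceptance is `distance <= cutoff`).
#' @param ligand1,receptor1,ligand2,receptor2 Atom selectors overriding the
#'   defaults described above.
#' @param triad Named integer vector of catalytic-triad residue numbers.
#' @return A list of class `criteria_spec`.
#' @export
criteria_spec <- function(cutoff1 = 5, cutoff2 = 5,
                          ligand1 = list(element = "S"),
                          receptor1 = NULL,
                          ligand2 = list(element = "O"),
                          receptor2 = NULL,
                          triad = c(SER = 40L, ASP = 318L, HIS = 321L)) {
  if (cutoff1 <= 0 || cutoff2 <= 0) abort("cutoffs must be positive.")
  if (is.null(receptor1)) {
    receptor1 <- list(residue_number = unname(triad[length(triad)]),
                      atom_name = "^CE1$")
  }
  if (is.null(receptor2)) {
    receptor2 <- list(residue_number = unname(triad), heavy = TRUE)
  }
  structure(list(
    stage1 = list(ligand = ligand1, receptor = receptor1, cutoff = cutoff1),
    stage2 = list(ligand = ligand2, receptor = receptor2, cutoff = cutoff2),
    triad = triad
  ), class = "criteria_spec")
}

#' Select atoms matching a selector
#'
#' @param atoms Atom tibble (`structure_model` or pose rows).
#' @param selector Selector list; see [criteria_spec()].
#' @param what Label used in the error message when nothing matches.
#' @return The matching rows.
#' @export
select_atoms <- function(atoms, selector, what = "selector") {
  keep <- rep(TRUE, nrow(atoms))
  if (!is.null(selector$element)) {
    keep <- keep & toupper(atoms$element) %in% toupper(selector$element)
  }
  if (!is.null(selector$atom_name)) {
    keep <- keep & grepl(selector$atom_name, atoms$atom_name)
  }
  if (!is.null(selector$residue_number) && "residue_number" %in% names(atoms)) {
    keep <- keep & atoms$residue_number %in% selector$residue_number
  }
  if (isTRUE(selector$heavy)) {
    keep <- keep & toupper(atoms$element) != "H"
  }
  out <- atoms[keep, , drop = FALSE]
  if (nrow(out) == 0) {
    abort(paste0("atom ", what, " matched no atoms (",
                 paste(names(selector), unlist(selector), sep = "=",
                       collapse = ", "), ")."))
  }
  out
}

#' Minimum inter-set atomic distance
#'
#' Minimum Euclidean distance over all cross pairs between two atom tables,
#' in Angstrom. Symmetric in its arguments.
#'
#' @param atoms_a,atoms_b Non-empty atom tibbles with `x`, `y`, `z` columns.
#' @return Single non-negative number.
#' @export
min_distance <- function(atoms_a, atoms_b) {
  if (nrow(atoms_a) == 0 || nrow(atoms_b) == 0) {
    abort("empty atom selection in min_distance().")
  }
  a <- as.matrix(atoms_a[, c("x", "y", "z")])
  b <- as.matrix(atoms_b[, c("x", "y", "z")])
  d2 <- outer(rowSums(a^2), rowSums(b^2), "+") - 2 * tcrossprod(a, b)
  sqrt(max(min(d2), 0))
}

# heavy atoms of the triad residues of a structure model
triad_atoms <- function(s, triad = attr(s, "triad")) {
  select_atoms(s, list(residue_number = unname(triad), heavy = TRUE),
               what = "catalytic triad")
}

#' Distance from a residue to the catalytic triad
#'
#' Minimum heavy-atom distance between one residue and the union of the
#' triad residues' heavy atoms; zero for a triad residue itself.
#'
#' @param s A `structure_model`.
#' @param residue_number Residue to measure.
#' @param triad Triad residue numbers (defaults to the model's own).
#' @return Distance in Angstrom.
#' @export
residue_triad_distance <- function(s, residue_number,
                                   triad = attr(s, "triad")) {
  res <- s[s$residue_number == residue_number & toupper(s$element) != "H", ,
           drop = FALSE]
  if (nrow(res) == 0) {
    abort(paste0("residue ", residue_number, " not found in structure."))
  }
  min_distance(res, triad_atoms(s, triad))
}

#' Distances of every residue to the catalytic triad
#'
#' @param s A `structure_model`.
#' @param triad Triad residue numbers (defaults to the model's own).
#' @return Tibble `residue_number`, `residue_name`, `triad_distance`, one
#'   row per residue.
#' @export
triad_distance_profile <- function(s, triad = attr(s, "triad")) {
  anchor <- triad_atoms(s, triad)
  s |>
    dplyr::filter(toupper(.data$element) != "H") |>
    dplyr::group_by(.data$residue_number, .data$residue_name) |>
    dplyr::summarise(triad_distance = min_distance(dplyr::pick("x", "y", "z"),
                                                   anchor),
                     .groups = "drop") |>
    dplyr::arrange(.data$residue_number)
}

# distance + acceptance for every pose in a pose table at one stage
pose_acceptance <- function(s, poses, criteria, stage = c("stage1", "stage2")) {
  stage <- match.arg(stage)
  st <- criteria[[stage]]
  receptor <- select_atoms(s, st$receptor, what = paste0(stage, " receptor"))
  poses |>
    dplyr::group_by(.data$pose_rank) |>
    dplyr::group_map(function(p, key) {
      lig <- select_atoms(p, st$ligand, what = paste0(stage, " ligand"))
      tibble::tibble(pose_rank = key$pose_rank,
                     distance = min_distance(lig, receptor))
    }) |>
    purrr::list_rbind() |>
    dplyr::mutate(accept = .data$distance <= st$cutoff)
}

#' Stage-1 acceptance of substrate-1 poses
#'
#' A pose is accepted when the minimum distance between its selected ligand
#' atoms (default: the thioester sulfur) and the selected receptor atoms
#' (default: His C-2, atom `CE1`) is at most the stage-1 cutoff. The
#' distance is always returned for audit.
#'
#' @param s A `structure_model`.
#' @param poses Pose tibble (possibly many poses; see [read_poses()]).
#' @param criteria A [criteria_spec()].
#' @return Tibble `pose_rank`, `distance`, `accept`.
#' @export
stage1_accept <- function(s, poses, criteria = criteria_spec()) {
  pose_acceptance(s, poses, criteria, "stage1")
}

#' Stage-2 acceptance of substrate-2 poses
#'
#' Default criterion: the reactive hydroxyl oxygen within the stage-2
#' cutoff of any heavy atom of the catalytic triad.
#'
#' @inheritParams stage1_accept
#' @return Tibble `pose_rank`, `distance`, `accept`.
#' @export
stage2_accept <- function(s, poses, criteria = criteria_spec()) {
  pose_acceptance(s, poses, criteria, "stage2")
}

#' Is a (substrate-1, substrate-2) pose pair a reasonable model?
#'
#' `TRUE` iff the substrate-1 pose passes stage 1 AND the substrate-2 pose
#' passes stage 2 on the same structure model.
#'
#' @param s A `structure_model`.
#' @param pose1,pose2 Single-pose tibbles (one `pose_rank` each).
#' @param criteria A [criteria_spec()].
#' @return Logical scalar.
#' @export
reasonable_model <- function(s, pose1, pose2, criteria = criteria_spec()) {
  a1 <- pose_acceptance(s, pose1, criteria, "stage1")
  if (nrow(a1) != 1 || !a1$accept) return(FALSE)
  a2 <- pose_acceptance(s, pose2, criteria, "stage2")
  nrow(a2) == 1 && a2$accept
}

#' Count reasonable models for one protein variant
#'
#' For each structure model of the variant, every (substrate-1 pose,
#' substrate-2 pose) pair is audited against the two-stage criteria and the
#' pairs passing both stages are counted. Substrate-2 poses may be one pose
#' set per model (the default workflow: the alcohol substrate docked once
#' into each acyl-accepted model) or a list of pose sets keyed by the
#' stage-1-accepted pose rank (`poses2[[as.character(pose1_rank)]]`).
#'
#' @param variant_id Variant label (e.g. `"native"`, `"R153A"`).
#' @param models List; each element is a list with `structure` (a
#'   `structure_model`), `poses1` (pose tibble) and `poses2` (pose tibble,
#'   or named list of pose tibbles keyed by pose-1 rank).
#' @param criteria A [criteria_spec()].
#' @return Object of class `reasonable_count`: list with `variant_id`,
#'   `per_model` (tibble `model_rank`, `n_pose1`, `n_accept1`, `count`),
#'   `audit` (tibble `model_rank`, `pose1_rank`, `pose2_rank`, `d1`, `d2`,
#'   `reasonable`), `counts` (integer vector), `mean`, `sd` (sample, n-1)
#'   and `criteria`.
#' @export
count_reasonable <- function(variant_id, models, criteria = criteria_spec()) {
  if (length(models) == 0) abort("at least one structure model is required.")
  audits <- purrr::imap(models, function(mod, i) {
    rank <- attr(mod$structure, "model_rank")
    if (is.null(rank) || is.na(rank)) rank <- i
    if (is.null(mod$poses1) || nrow(mod$poses1) == 0) {
      warn(paste0("model ", rank, " of '", variant_id,
                  "' has no substrate-1 poses; count 0."))
      return(tibble::tibble(model_rank = integer(), pose1_rank = integer(),
                            pose2_rank = integer(), d1 = double(),
                            d2 = double(), reasonable = logical()))
    }
    a1 <- pose_acceptance(mod$structure, mod$poses1, criteria, "stage1")
    pose2_of <- function(p1_rank) {
      if (is.data.frame(mod$poses2)) mod$poses2
      else mod$poses2[[as.character(p1_rank)]]
    }
    purrr::map(a1$pose_rank, function(p1) {
      p2 <- pose2_of(p1)
      if (is.null(p2) || nrow(p2) == 0) {
        return(tibble::tibble(model_rank = as.integer(rank), pose1_rank = p1,
                              pose2_rank = NA_integer_,
                              d1 = a1$distance[a1$pose_rank == p1],
                              d2 = NA_real_, reasonable = FALSE))
      }
      a2 <- pose_acceptance(mod$structure, p2, criteria, "stage2")
      tibble::tibble(model_rank = as.integer(rank), pose1_rank = p1,
                     pose2_rank = a2$pose_rank,
                     d1 = a1$distance[a1$pose_rank == p1],
                     d2 = a2$distance,
                     reasonable = a1$accept[a1$pose_rank == p1] & a2$accept)
    }) |> purrr::list_rbind()
  })
  audit <- purrr::list_rbind(audits)
  ranks <- purrr::imap_int(models, function(mod, i) {
    r <- attr(mod$structure, "model_rank")
    if (is.null(r) || is.na(r)) as.integer(i) else as.integer(r)
  })
  per_model <- tibble::tibble(model_rank = ranks) |>
    dplyr::left_join(
      audit |>
        dplyr::group_by(.data$model_rank) |>
        dplyr::summarise(
          n_pose1 = dplyr::n_distinct(.data$pose1_rank),
          n_accept1 = dplyr::n_distinct(
            .data$pose1_rank[.data$d1 <= criteria$stage1$cutoff]),
          count = sum(.data$reasonable), .groups = "drop"),
      by = "model_rank") |>
    tidyr::replace_na(list(n_pose1 = 0L, n_accept1 = 0L, count = 0L))
  counts <- per_model$count
  structure(list(variant_id = variant_id, per_model = per_model,
                 audit = audit, counts = counts,
                 mean = mean(counts),
                 sd = if (length(counts) > 1) sd(counts) else 0,
                 criteria = criteria),
            class = "reasonable_count")
}

#' @export
print.reasonable_count <- function(x, ...) {
  cat(sprintf("<reasonable_count> %s: %.1f +/- %.1f over %d model(s) [counts: %s]\n",
              x$variant_id, x$mean, x$sd, length(x$counts),
              paste(x$counts, collapse = ", ")))
  invisible(x)
}

#' @rdname count_reasonable
#' @param x A `reasonable_count`.
#' @param ... Unused.
#' @method tidy reasonable_count
#' @export
tidy.reasonable_count <- function(x, ...) {
  dplyr::mutate(x$per_model, variant_id = x$variant_id, .before = 1)
}

#' @rdname count_reasonable
#' @method glance reasonable_count
#' @export
glance.reasonable_count <- function(x, ...) {
  tibble::tibble(variant_id = x$variant_id, n_models = length(x$counts),
                 mean = x$mean, sd = x$sd,
                 cutoff1 = x$criteria$stage1$cutoff,
                 cutoff2 = x$criteria$stage2$cutoff)
}
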