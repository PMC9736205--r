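#' Read a receptor structure model from PDB
#'
#' Parses ATOM/HETATM records (via \pkg{bio3d}) into a tidy atom table and
#' checks that the catalytic triad is present. The default triad is the
#' Ser40/Asp318/His321 numbering of the TciGLIP transferase; any renumbering
#' can be supplied.
#'
#' @param pdb_path Path to a PDB file.
#' @param triad Named integer vector of triad residue numbers; names are the
#'   expected residue names.
#' @param variant_id,model_rank Identifiers attached to the result (used in
#'   audit tables).
#' @return A tibble of class `structure_model` with columns `atom_name`,
#'   `residue_name`, `residue_number`, `chain`, `element`, `x`, `y`, `z` and
#'   attributes `variant_id`, `model_rank`, `triad`.
#' @export
read_structure <- function(pdb_path,
                           triad = c(SER = 40L, ASP = 318L, HIS = 321L),
                           variant_id = NA_character_, model_rank = NA_integer_) {
  pdb <- tryCatch(bio3d::read.pdb(pdb_path, verbose = FALSE),
                  error = function(e) abort(paste0("cannot parse PDB '",
                                                   pdb_path, "': ",
                                                   conditionMessage(e))))
  at <- pdb$atom
  atoms <- tibble::tibble(
    atom_name = at$elety,
    residue_name = at$resid,
    residue_number = as.integer(at$resno),
    chain = ifelse(is.na(at$chain), "A", at$chain),
    element = element_from_name(at$elesy, at$elety),
    x = at$x, y = at$y, z = at$z
  )
  if (any(!is.finite(atoms$x) | !is.finite(atoms$y) | !is.finite(atoms$z))) {
    abort("non-finite coordinates in structure.")
  }
  structure_model(atoms, triad = triad, variant_id = variant_id,
                  model_rank = model_rank)
}

#' Construct a structure model from an atom table
#'
#' @param atoms Tibble with columns `atom_name`, `residue_name`,
#'   `residue_number`, `chain`, `element`, `x`, `y`, `z`.
#' @inheritParams read_structure
#' @return A `structure_model` tibble.
#' @export
structure_model <- function(atoms,
                            triad = c(SER = 40L, ASP = 318L, HIS = 321L),
                            variant_id = NA_character_,
                            model_rank = NA_integer_) {
  atoms <- tibble::as_tibble(atoms)
  for (i in seq_along(triad)) {
    hit <- atoms$residue_number == triad[i] &
      atoms$residue_name == names(triad)[i]
    if (!any(hit)) {
      abort(paste0("catalytic triad residue ", names(triad)[i], " ",
                   triad[i], " not found."))
    }
  }
  attr(atoms, "triad") <- triad
  attr(atoms, "variant_id") <- variant_id
  attr(atoms, "model_rank") <- model_rank
  class(atoms) <- c("structure_model", class(atoms))
  atoms
}

# derive the element symbol, preferring an explicit element column and
# falling back to the first alphabetic character of the atom name
element_from_name <- function(element, atom_name) {
  el <- toupper(trimws(element))
  fallback <- toupper(substr(gsub("[^A-Za-z].*$", "",
                                  sub("^[0-9]+", "", trimws(atom_name))), 1, 1))
  ifelse(is.na(el) | el == "", fallback, el)
}

# AutoDock atom types that differ from the plain element symbol
ADTYPE_TO_ELEMENT <- c(A = "C", NA_ = "N", OA = "O", SA = "S", HD = "H",
                       HS = "H", NS = "N", CL = "CL", BR = "BR", FE = "FE",
                       MG = "MG", MN = "MN", ZN = "ZN")

adtype_element <- function(adtype) {
  key <- toupper(trimws(adtype))
  key[key == "NA"] <- "NA_"
  mapped <- ADTYPE_TO_ELEMENT[key]
  out <- ifelse(is.na(mapped), toupper(trimws(adtype)), mapped)
  # single-letter types are already elements
  out[out == ""] <- NA_character_
  out
}

#' Read docked ligand poses (PDBQT or multi-model PDB)
#'
#' Docking engines emit one `MODEL`/`ENDMDL` block per pose, ranked by
#' score; a file without `MODEL` records is treated as a single pose.
#' PDBQT ATOM records share the PDB fixed columns for name and coordinates
#' and carry an AutoDock atom type in place of the element symbol; the type
#' is translated back to an element (e.g. `SA` to S, `OA` to O). No
#' installed reader handles PDBQT torsion-tree records, so this parser is
#' implemented here on the fixed-column layout.
#'
#' @param path Path to a PDBQT or (multi-model) PDB pose file.
#' @param substrate_id Identifier stored alongside each pose.
#' @return Tibble with columns `pose_rank`, `atom_name`, `residue_name`,
#'   `element`, `x`, `y`, `z` and attribute `substrate_id`.
#' @export
read_poses <- function(path, substrate_id = NA_character_) {
  lines <- readLines(path)
  starts <- grep("^MODEL", lines)
  if (length(starts) == 0) {
    blocks <- list(lines)
  } else {
    ends <- grep("^ENDMDL", lines)
    if (length(ends) != length(starts)) {
      abort("unbalanced MODEL/ENDMDL blocks.")
    }
    blocks <- purrr::map2(starts, ends, function(s, e) lines[(s + 1):(e - 1)])
  }
  if (length(blocks) > 20) {
    warn(paste0(length(blocks), " pose models found (docking num_modes ",
                "maximum is 20); keeping all."))
  }
  poses <- purrr::imap(blocks, function(block, rank) {
    atom_lines <- grep("^(ATOM|HETATM)", block, value = TRUE)
    if (length(atom_lines) == 0) return(NULL)
    parse_atom_lines(atom_lines, path) |>
      dplyr::mutate(pose_rank = as.integer(rank), .before = 1)
  })
  poses <- purrr::compact(poses)
  if (length(poses) == 0) abort(paste0("zero pose models in '", path, "'."))
  out <- purrr::list_rbind(poses)
  attr(out, "substrate_id") <- substrate_id
  out
}

# fixed-column ATOM/HETATM parser shared by PDB and PDBQT pose blocks
parse_atom_lines <- function(atom_lines, path) {
  xs <- suppressWarnings(as.numeric(substr(atom_lines, 31, 38)))
  ys <- suppressWarnings(as.numeric(substr(atom_lines, 39, 46)))
  zs <- suppressWarnings(as.numeric(substr(atom_lines, 47, 54)))
  if (anyNA(xs) || anyNA(ys) || anyNA(zs)) {
    bad <- which(is.na(xs) | is.na(ys) | is.na(zs))[1]
    abort(paste0("unparsable ATOM record in '", path, "' (atom line ", bad,
                 "): ", atom_lines[bad]))
  }
  tail_field <- trimws(substr(atom_lines, 77, 79))
  name <- trimws(substr(atom_lines, 13, 16))
  element <- ifelse(tail_field == "",
                    element_from_name(NA_character_, name),
                    adtype_element(tail_field))
  tibble::tibble(
    atom_name = name,
    residue_name = trimws(substr(atom_lines, 18, 20)),
    element = element,
    x = xs, y = ys, z = zs
  )
}

# minimal fixed-column ATOM line, shared by the PDB and PDBQT writers;
# `tail` is the element symbol (PDB) or charge + AutoDock type (PDBQT)
format_atom_line <- function(i, atom_name, residue_name, residue_number,
                             chain, x, y, z, tail) {
  name_field <- if (nchar(atom_name) < 4) sprintf(" %-3s", atom_name) else atom_name
  sprintf("ATOM  %5d %4s %-3s %1s%4d    %8.3f%8.3f%8.3f  1.00  0.00%s",
          i, name_field, residue_name, chain, residue_number, x, y, z, tail)
}

#' Write a structure model to PDB
#'
#' @param s A `structure_model` (or compatible atom tibble).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_structure <- function(s, path) {
  lines <- purrr::pmap_chr(
    list(seq_len(nrow(s)), s$atom_name, s$residue_name, s$residue_number,
         if (is.null(s$chain)) rep("A", nrow(s)) else s$chain, s$x, s$y, s$z, sprintf("          %2s", s$element)),
    format_atom_line)
  writeLines(c(lines, "END"), path)
  invisible(path)
}

# element -> AutoDock atom type used when writing PDBQT
element_adtype <- function(element) {
  dplyr::case_match(toupper(element),
                    "S" ~ "SA", "O" ~ "OA", "H" ~ "HD",
                    .default = toupper(element))
}

#' Write docked poses as a multi-model PDBQT file
#'
#' @param poses Tibble from [read_poses()] / [simulate_poses()]: columns
#'   `pose_rank`, `atom_name`, `residue_name`, `element`, `x`, `y`, `z`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_poses <- function(poses, path) {
  blocks <- poses |>
    dplyr::group_by(.data$pose_rank) |>
    dplyr::group_map(function(p, key) {
      lines <- purrr::pmap_chr(
        list(seq_len(nrow(p)), p$atom_name,
             p$residue_name %||% rep("LIG", nrow(p)), rep(1L, nrow(p)),
             rep("A", nrow(p)), p$x, p$y, p$z,
             sprintf("    %6.3f %-2s", 0, element_adtype(p$element))),
        format_atom_line)
      c(sprintf("MODEL %8d", key$pose_rank), lines, "ENDMDL")
    })
  writeLines(unlist(blocks), path)
  invisible(path)
}
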