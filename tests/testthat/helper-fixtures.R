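# shared fixtures and independent oracles, built in code at test time

tiny_alignment <- function() {
  labeled_alignment(c("A", "B"), c("M-KL", "MAKL"), c("tr", "est"))
}

# random gapped alignment; returns a labeled_alignment
random_alignment <- function(n_seq, n_col, gap_prob = 0.2, seed = 1,
                             groups = NULL) {
  set.seed(seed)
  pool <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
            "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")
  m <- matrix(sample(pool, n_seq * n_col, replace = TRUE), n_seq, n_col)
  m[matrix(runif(n_seq * n_col) < gap_prob, n_seq, n_col)] <- "-"
  # keep at least one residue per sequence so residue_to_column is testable
  m[, 1] <- sample(pool, n_seq, replace = TRUE)
  if (is.null(groups)) {
    groups <- rep(c("tr", "est", "putative"), length.out = n_seq)
  }
  labeled_alignment(paste0("s", seq_len(n_seq)),
                    apply(m, 1, paste, collapse = ""), groups)
}

# naive reimplementation of the per-column two-entropy calculation:
# explicit loops over columns, residues and the pseudo-count mix
naive_entropy_profile <- function(aln, pc, strict_nall = FALSE) {
  alphabet <- pc$alphabet
  rows <- strsplit(aln$seq, "")
  n_col <- nchar(aln$seq[1])
  one_group <- function(which_rows) {
    vapply(seq_len(n_col), function(p) {
      counts <- setNames(numeric(20), alphabet)
      for (i in which_rows) {
        ch <- rows[[i]][p]
        if (ch %in% alphabet) counts[ch] <- counts[ch] + 1
      }
      n_obs <- sum(counts)
      if (n_obs == 0) {
        f <- pc$background
      } else {
        f <- numeric(20)
        for (a in seq_len(20)) {
          mix <- 0
          for (b in seq_len(20)) {
            mix <- mix + (counts[b] / n_obs) * pc$cond[a, b]
          }
          denom <- if (strict_nall) length(which_rows) + pc$B
                   else n_obs + pc$B
          f[a] <- (counts[a] + pc$B * mix) / denom
        }
      }
      e <- 0
      for (a in seq_len(20)) if (f[a] > 0) e <- e - f[a] * log10(f[a])
      e
    }, numeric(1))
  }
  e_tr <- one_group(which(aln$group == "tr"))
  e_other <- one_group(which(aln$group %in% c("est", "putative")))
  tibble::tibble(column = seq_len(n_col), E_tr = e_tr, E_other = e_other,
                 delta = e_other - e_tr)
}

# minimal synthetic structure with the catalytic triad plus one distal residue
tiny_structure <- function(extra = NULL) {
  atoms <- tibble::tribble(
    ~atom_name, ~residue_name, ~residue_number, ~chain, ~element, ~x, ~y, ~z,
    "CA",  "SER", 40L,  "A", "C", 0,   0,   0,
    "OG",  "SER", 40L,  "A", "O", 1.4, 0.5, 0,
    "CA",  "ASP", 318L, "A", "C", 4,   0,   0,
    "OD1", "ASP", 318L, "A", "O", 5.2, 0.8, 0,
    "CA",  "HIS", 321L, "A", "C", 0,   4,   0,
    "CE1", "HIS", 321L, "A", "C", 1.0, 5.0, 0
  )
  if (!is.null(extra)) atoms <- dplyr::bind_rows(atoms, extra)
  structure_model(atoms)
}

# single-atom pose table builders
one_atom_pose <- function(pose_rank, element, x, y, z,
                          atom_name = paste0(element, "1")) {
  tibble::tibble(pose_rank = as.integer(pose_rank), atom_name = atom_name,
                 residue_name = "LIG", element = element, x = x, y = y, z = z)
}

# a proper rigid-body transform: rotation about an arbitrary axis + shift
rigid_transform <- function(df, angle = 0.7, axis = c(1, 2, 3),
                            shift = c(10, -5, 3)) {
  u <- axis / sqrt(sum(axis^2))
  c0 <- cos(angle); s0 <- sin(angle)
  rot <- c0 * diag(3) + s0 * rbind(c(0, -u[3], u[2]),
                                   c(u[3], 0, -u[1]),
                                   c(-u[2], u[1], 0)) +
    (1 - c0) * outer(u, u)
  xyz <- as.matrix(df[, c("x", "y", "z")]) %*% t(rot)
  df$x <- xyz[, 1] + shift[1]
  df$y <- xyz[, 2] + shift[2]
  df$z <- xyz[, 3] + shift[3]
  df
}

transform_model <- function(mod, ...) {
  s <- rigid_transform(mod$structure, ...)
  attr(s, "triad") <- attr(mod$structure, "triad")
  class(s) <- class(mod$structure)
  list(structure = s,
       poses1 = rigid_transform(mod$poses1, ...),
       poses2 = rigid_transform(mod$poses2, ...))
}
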