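test_that("structure round-trips through PDB at coordinate precision", {
  s <- tiny_structure()
  pdb <- withr::local_tempfile(fileext = ".pdb")
  write_structure(s, pdb)
  back <- read_structure(pdb)
  expect_equal(nrow(back), nrow(s))
  expect_equal(back$x, s$x, tolerance = 1e-3)
  expect_equal(back$y, s$y, tolerance = 1e-3)
  expect_equal(back$z, s$z, tolerance = 1e-3)
  expect_equal(back$atom_name, s$atom_name)
  expect_equal(sort(unique(back$residue_number)), c(40L, 318L, 321L))
})

test_that("a structure lacking a triad residue is rejected by name", {
  s <- tiny_structure()
  no_his <- s[s$residue_number != 321, ]
  pdb <- withr::local_tempfile(fileext = ".pdb")
  write_structure(no_his, pdb)
  expect_error(read_structure(pdb), "HIS 321 not found")
})

test_that("pose files parse with rank order, dialect tolerance and element mapping", {
  poses <- dplyr::bind_rows(lapply(1:20, function(i)
    one_atom_pose(i, "S", i, 0, 0)))
  f <- withr::local_tempfile(fileext = ".pdbqt")
  write_poses(poses, f)
  back <- read_poses(f)
  expect_equal(unique(back$pose_rank), 1:20)
  expect_equal(unique(back$element), "S")

  # single unwrapped pose without MODEL records
  raw <- withr::local_tempfile(fileext = ".pdbqt")
  writeLines(c(
    "ATOM      1  S1  LIG A   1       1.000   2.000   3.000  1.00  0.00     0.000 SA",
    "ATOM      2  C1  LIG A   1       2.500   2.000   3.000  1.00  0.00     0.000 C"),
    raw)
  one <- read_poses(raw)
  expect_equal(unique(one$pose_rank), 1L)
  expect_equal(one$element, c("S", "C"))
  expect_equal(one$x, c(1, 2.5))

  # element extraction agrees with a naive column parser on the same file
  lines <- grep("^ATOM", readLines(f), value = TRUE)
  naive_type <- trimws(substring(lines, 77, 79))
  naive_el <- ifelse(naive_type == "SA", "S", naive_type)
  expect_equal(back$element, naive_el)

  # more than 20 models warns; zero models errors
  many <- dplyr::bind_rows(lapply(1:21, function(i) one_atom_pose(i, "C", i, 0, 0)))
  f2 <- withr::local_tempfile(fileext = ".pdbqt")
  write_poses(many, f2)
  expect_warning(all21 <- read_poses(f2), "20")
  expect_equal(length(unique(all21$pose_rank)), 21)
  empty <- withr::local_tempfile(fileext = ".pdbqt")
  writeLines("REMARK nothing", empty)
  expect_error(read_poses(empty), "zero pose")
})

test_that("min_distance is the brute-force cross-pair minimum", {
  a <- one_atom_pose(1, "S", 0, 0, 0)
  b <- one_atom_pose(1, "C", 3, 4, 0)
  expect_equal(min_distance(a, b), 5)
  expect_equal(min_distance(b, a), 5)
  expect_equal(min_distance(a, a), 0)

  set.seed(2)
  am <- tibble::tibble(x = rnorm(10), y = rnorm(10), z = rnorm(10))
  bm <- tibble::tibble(x = rnorm(12), y = rnorm(12), z = rnorm(12))
  brute <- Inf
  for (i in 1:10) for (j in 1:12) {
    brute <- min(brute, sqrt((am$x[i] - bm$x[j])^2 + (am$y[i] - bm$y[j])^2 +
                               (am$z[i] - bm$z[j])^2))
  }
  expect_equal(min_distance(am, bm), brute, tolerance = 1e-12)
  expect_error(min_distance(am[0, ], bm), "empty")
})

test_that("residue-to-triad distances include the self-distance zero", {
  far <- tibble::tibble(atom_name = "CA", residue_name = "GLY",
                        residue_number = 100L, chain = "A", element = "C",
                        x = 0, y = 0, z = 10)
  s <- tiny_structure(extra = far)
  expect_equal(residue_triad_distance(s, 321), 0)
  expect_equal(residue_triad_distance(s, 100), 10, tolerance = 1e-6)
  expect_error(residue_triad_distance(s, 999), "not found")
  prof <- triad_distance_profile(s)
  brute <- min(sqrt((s$x - 0)^2 + (s$y - 0)^2 + (s$z - 10)^2))
  expect_equal(prof$triad_distance[prof$residue_number == 100], 10,
               tolerance = 1e-6)
  expect_equal(prof$triad_distance[prof$residue_number %in% c(40, 318, 321)],
               rep(0, 3))
})

test_that("stage-1 acceptance uses a strict <= cutoff on the S-to-CE1 distance", {
  s <- tiny_structure()
  ce1 <- s[s$atom_name == "CE1", ]
  near <- one_atom_pose(1, "S", ce1$x + 4, ce1$y, ce1$z)
  boundary <- one_atom_pose(2, "S", ce1$x + 5.0001, ce1$y, ce1$z)
  acc <- stage1_accept(s, dplyr::bind_rows(near, boundary), criteria_spec())
  expect_equal(acc$accept, c(TRUE, FALSE))
  expect_equal(acc$distance, c(4, 5.0001), tolerance = 1e-9)
  # exact-boundary pose is accepted (<=)
  at5 <- one_atom_pose(3, "S", ce1$x + 5, ce1$y, ce1$z)
  expect_true(stage1_accept(s, at5)$accept)
  # selector that matches nothing errors informatively
  expect_error(stage1_accept(s, one_atom_pose(1, "C", 0, 0, 0)), "ligand")
})

test_that("reasonable_model is the conjunction of the two stages", {
  s <- tiny_structure()
  ce1 <- s[s$atom_name == "CE1", ]
  p1_ok <- one_atom_pose(1, "S", ce1$x + 3, ce1$y, ce1$z)
  p2_ok <- one_atom_pose(1, "O", 1, 1, 1)
  p2_far <- one_atom_pose(2, "O", 100, 100, 100)
  expect_true(reasonable_model(s, p1_ok, p2_ok))
  expect_false(reasonable_model(s, p1_ok, p2_far))
  p1_far <- one_atom_pose(2, "S", ce1$x + 50, ce1$y, ce1$z)
  expect_false(reasonable_model(s, p1_far, p2_ok))
})

test_that("counts decompose as accepted-pose products and summaries recompute", {
  sim <- simulate_poses(pose_sim_spec(n_models = 3, seed = 31,
                                      accept_frac1 = 0.5, accept_frac2 = 0.5))
  rc <- count_reasonable("native", sim$models)
  # per-model count equals (#stage1 accepted) x (#stage2 accepted) from truth
  tr <- sim$truth
  for (m in 1:3) {
    n1 <- sum(tr$accept[tr$model_rank == m & tr$substrate == "substrate1"])
    n2 <- sum(tr$accept[tr$model_rank == m & tr$substrate == "substrate2"])
    expect_equal(rc$per_model$count[rc$per_model$model_rank == m], n1 * n2)
  }
  # audit covers every pair, and counts equal audit tallies
  expect_equal(nrow(rc$audit), 3 * 20 * 20)
  expect_equal(sum(rc$audit$reasonable), sum(rc$per_model$count))
  # summary fields recompute from the per-model counts
  expect_equal(rc$mean, mean(rc$per_model$count))
  expect_equal(rc$sd, sd(rc$per_model$count))
  expect_equal(glance(rc)$mean, rc$mean)
  expect_equal(tidy(rc)$count, rc$per_model$count)
})

test_that("count_reasonable handles constant, empty and per-pose substrate-2 inputs", {
  s <- tiny_structure()
  ce1 <- s[s$atom_name == "CE1", ]
  p1 <- one_atom_pose(1, "S", ce1$x + 2, ce1$y, ce1$z)
  p2 <- one_atom_pose(1, "O", 1, 1, 1)
  models <- replicate(5, list(structure = s, poses1 = p1, poses2 = p2),
                      simplify = FALSE)
  rc <- count_reasonable("v", models)
  expect_equal(rc$counts, rep(1L, 5))
  expect_equal(rc$mean, 1)
  expect_equal(rc$sd, 0)

  expect_warning(
    rc0 <- count_reasonable("v", list(list(structure = s,
                                           poses1 = p1[0, ], poses2 = p2))),
    "no substrate-1")
  expect_equal(rc0$counts, 0L)

  # substrate-2 pose sets keyed by accepted substrate-1 pose
  p1b <- dplyr::bind_rows(p1, one_atom_pose(2, "S", ce1$x + 3, ce1$y, ce1$z))
  keyed <- list(`1` = p2,
                `2` = dplyr::bind_rows(p2, one_atom_pose(2, "O", 90, 0, 0)))
  rck <- count_reasonable("v", list(list(structure = s, poses1 = p1b,
                                         poses2 = keyed)))
  expect_equal(rck$counts, 2L)  # pose1=1 x 1 accepted + pose1=2 x 1 accepted
})

test_that("acceptance decisions are invariant under rigid-body motion and monotone in cutoffs", {
  sim <- simulate_poses(pose_sim_spec(n_models = 2, seed = 77,
                                      accept_frac1 = 0.5, accept_frac2 = 0.5))
  crit <- criteria_spec()
  for (mod in sim$models) {
    moved <- transform_model(mod, angle = 1.1, axis = c(2, -1, 1),
                             shift = c(-7, 12, 4))
    a_orig <- stage1_accept(mod$structure, mod$poses1, crit)
    a_moved <- stage1_accept(moved$structure, moved$poses1, crit)
    expect_equal(a_orig$distance, a_moved$distance, tolerance = 1e-6)
    expect_equal(a_orig$accept, a_moved$accept)
    b_orig <- stage2_accept(mod$structure, mod$poses2, crit)
    b_moved <- stage2_accept(moved$structure, moved$poses2, crit)
    expect_equal(b_orig$distance, b_moved$distance, tolerance = 1e-6)
  }
  # enlarging cutoffs never decreases counts; degenerate tiny cutoff gives 0
  counts_at <- function(c1, c2) {
    count_reasonable("v", sim$models,
                     criteria_spec(cutoff1 = c1, cutoff2 = c2))$counts
  }
  base <- counts_at(5, 5)
  expect_true(all(counts_at(8, 5) >= base))
  expect_true(all(counts_at(5, 8) >= base))
  expect_true(all(counts_at(12, 12) >= counts_at(8, 8)))
  expect_equal(counts_at(1e-9, 1e-9), rep(0L, 2))
})
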