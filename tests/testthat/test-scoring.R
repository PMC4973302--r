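# Clash and hydrogen-bond scoring: strict/closed boundaries, oracle
# equality of the two code paths, invariances and the winner rule.

td_box_protein <- function() {
  ## 27 carbon atoms on a 3x3x3 lattice, 4 A apart, centred at origin
  g <- expand.grid(x = c(-4, 0, 4), y = c(-4, 0, 4), z = c(-4, 0, 4))
  td_protein(as.matrix(g), resname = "BOX", polar_role = "none")
}

test_that("a far-away ligand scores zero clashes", {
  prot <- td_box_protein()
  p <- td_pose(matrix(c(100, 100, 100), ncol = 3))
  expect_identical(clash_score(p, prot), 0L)
  expect_identical(clash_score(p, prot, method = "exhaustive"), 0L)
})

test_that("the clash threshold is a strict inequality", {
  prot <- td_protein(c(0, 0, 0))
  at_threshold <- td_pose(matrix(c(3, 0, 0), ncol = 3))
  inside <- td_pose(matrix(c(2.9, 0, 0), ncol = 3))
  for (m in c("grid", "exhaustive")) {
    expect_identical(clash_score(at_threshold, prot, method = m), 0L)
    expect_identical(clash_score(inside, prot, method = m), 1L)
  }
})

test_that("clash counts match a manual all-pairs enumeration", {
  set.seed(11)
  prot_xyz <- matrix(runif(36, -4, 4), ncol = 3)
  prot <- td_protein(prot_xyz, polar_role = "none")
  lig_xyz <- matrix(runif(15, -4, 4), ncol = 3)
  p <- td_pose(lig_xyz)
  d <- as.matrix(stats::dist(rbind(lig_xyz, prot_xyz)))[1:5, 6:17]
  expect_identical(clash_score(p, prot), as.integer(sum(d < 3.0)))
  expect_identical(clash_score(p, prot, method = "exhaustive"),
                   as.integer(sum(d < 3.0)))
  expect_identical(clash_score(p, prot, per = "atom"),
                   as.integer(sum(rowSums(d < 3.0) > 0)))
})

test_that("per-atom counting collapses multiple contacts of one atom", {
  prot <- td_protein(matrix(c(0, 0, 0, 1, 0, 0), ncol = 3, byrow = TRUE),
                     resseq = 1:2)
  p <- td_pose(matrix(c(0.5, 1, 0), ncol = 3))
  expect_identical(clash_score(p, prot, per = "pair"), 2L)
  expect_identical(clash_score(p, prot, per = "atom"), 1L)
})

test_that("solvent is excluded from clash scoring unless requested", {
  prot <- td_protein(matrix(c(0, 0, 0, 1, 0, 0), ncol = 3, byrow = TRUE),
                     resname = c("ALA", "HOH"),
                     element = c("C", "O"), resseq = 1:2)
  p <- td_pose(matrix(c(1.5, 0, 0), ncol = 3))
  expect_identical(clash_score(p, prot), 1L)
  expect_identical(clash_score(p, prot, include_solvent = TRUE), 2L)
})

test_that("the hydrogen-bond window is closed at both ends", {
  prot <- td_protein(c(0, 0, 0), name = "OG", element = "O",
                     resname = "SER", polar_role = "both")
  at <- function(d) td_pose(matrix(c(d, 0, 0), ncol = 3), hydroxyl = 1L,
                            names = "O1")
  for (m in c("grid", "exhaustive")) {
    expect_identical(hbond_score(at(2.0), prot, method = m)$count, 1L)
    expect_identical(hbond_score(at(4.2), prot, method = m)$count, 1L)
    expect_identical(hbond_score(at(3.0), prot, method = m)$count, 1L)
    expect_identical(hbond_score(at(1.9), prot, method = m)$count, 0L)
    expect_identical(hbond_score(at(4.3), prot, method = m)$count, 0L)
  }
})

test_that("hbond partners report resolvable atoms and in-window distances", {
  prot <- td_protein(matrix(c(0, 0, 0, 3, 0, 0, 3, 2.5, 0),
                            ncol = 3, byrow = TRUE),
                     name = c("OG", "CB", "N"),
                     element = c("O", "C", "N"),
                     resname = c("SER", "SER", "GLY"), resseq = c(1, 1, 2),
                     polar_role = c("both", "none", "donor"))
  p <- td_pose(matrix(c(0, 2.5, 0, 50, 50, 50), ncol = 3, byrow = TRUE),
               hydroxyl = c(1L, 2L), names = c("O1", "O2"))
  hb <- hbond_score(p, prot)
  expect_identical(hb$count, 2L)   # OG and N are in window; CB is not polar
  expect_identical(nrow(hb$partners), 2L)
  expect_identical(hb$partners$hydroxyl, c("O1", "O1"))
  expect_setequal(hb$partners$protein_atom, c("SER1:OG", "GLY2:N"))
  expect_true(all(hb$partners$distance >= 2.0 &
                    hb$partners$distance <= 4.2))
})

test_that("unassigned polar roles and missing hydroxyls are errors", {
  prot <- td_protein(c(0, 0, 0), element = "O", name = "O")  # role NA
  p <- td_pose(matrix(c(3, 0, 0), ncol = 3), hydroxyl = 1L)
  expect_error(hbond_score(p, prot), "polar roles are not assigned")
  prot2 <- td_protein(c(0, 0, 0), polar_role = "none")
  expect_error(hbond_score(td_pose(matrix(c(3, 0, 0), ncol = 3)), prot2),
               "no annotated hydroxyl")
})

test_that("prebuilt indices must cover the cutoff in play", {
  prot <- td_protein(c(0, 0, 0), polar_role = "both", element = "O")
  p <- td_pose(matrix(c(2.5, 0, 0), ncol = 3), hydroxyl = 1L)
  idx <- scoring_index(atom_xyz(prot), cell = 2.0)
  expect_error(clash_score(p, prot, threshold = 3.0, index = idx),
               "smaller than threshold")
  expect_error(hbond_score(p, prot, index = idx),
               "smaller than the window upper bound")
  expect_error(scoring_index(atom_xyz(prot), cell = 0), "cell > 0")
})

test_that("grid and exhaustive paths agree on random synthetic poses", {
  tun <- make_tunnel_protein(tunnel_spec())
  lib <- make_ligand_library(ligand_spec(n_conformers = 8L, seed = 21L))
  poses <- td_random_poses(lib, 30, seed = 21)
  for (p in poses) {
    expect_identical(clash_score(p, tun$structure, method = "grid"),
                     clash_score(p, tun$structure, method = "exhaustive"))
    expect_identical(hbond_score(p, tun$structure, method = "grid")$count,
                     hbond_score(p, tun$structure,
                                 method = "exhaustive")$count)
  }
})

test_that("scores are invariant under a joint rigid transform", {
  tun <- make_tunnel_protein(tunnel_spec())
  lib <- make_ligand_library(ligand_spec(n_conformers = 4L, seed = 31L))
  poses <- td_random_poses(lib, 6, seed = 31)
  set.seed(32)
  tr <- rigid_transform(td_random_rotation(), rnorm(3, 0, 25))
  prot2 <- td_transform_protein(tun$structure, tr)
  for (p in poses) {
    p2 <- p
    p2$xyz <- apply_transform(tr, p$xyz)
    expect_identical(clash_score(p, tun$structure),
                     clash_score(p2, prot2))
    expect_identical(hbond_score(p, tun$structure)$count,
                     hbond_score(p2, prot2)$count)
  }
})

test_that("counts are monotone in their thresholds", {
  tun <- make_tunnel_protein(tunnel_spec())
  lib <- make_ligand_library(ligand_spec(n_conformers = 4L, seed = 41L))
  poses <- td_random_poses(lib, 8, seed = 41)
  for (p in poses) {
    expect_lte(clash_score(p, tun$structure, threshold = 2.5),
               clash_score(p, tun$structure, threshold = 3.0))
    expect_lte(hbond_score(p, tun$structure, window = c(2.0, 4.2))$count,
               hbond_score(p, tun$structure, window = c(1.5, 5.0))$count)
  }
})

test_that("score_ensemble emits one record per pose in pose order", {
  tun <- make_tunnel_protein(tunnel_spec())
  lspec <- ligand_spec(n_conformers = 4L)
  lib <- make_ligand_library(lspec)
  tpl <- make_templates(tun$metadata, lspec)
  ps <- build_ensemble(tpl, lib)
  rec <- score_ensemble(ps, tun$structure)
  expect_identical(nrow(rec), length(ps$poses))
  expect_identical(rec$pose_id, vapply(ps$poses, `[[`, "", "pose_id"))
  expect_identical(names(rec), c("pose_id", "template", "conformer",
                                 "orientation", "clashes", "hbonds",
                                 "model"))
  expect_type(rec$clashes, "integer")
  expect_type(rec$hbonds, "integer")
  expect_identical(unique(rec$model), "base")
  rec2 <- score_ensemble(ps, tun$structure, method = "exhaustive")
  expect_identical(rec$clashes, rec2$clashes)
  expect_identical(rec$hbonds, rec2$hbonds)
})

test_that("pick_winner minimises clashes with hbond and id tie-breaks", {
  rec <- data.frame(pose_id = c("p1", "p2", "p3"),
                    clashes = c(5L, 3L, 9L), hbonds = c(0L, 1L, 4L),
                    stringsAsFactors = FALSE)
  expect_identical(pick_winner(rec)$pose_id, "p2")
  tie <- data.frame(pose_id = c("p1", "p2"), clashes = c(2L, 2L),
                    hbonds = c(1L, 2L), stringsAsFactors = FALSE)
  expect_identical(pick_winner(tie)$pose_id, "p2")
  tie2 <- data.frame(pose_id = c("b", "a"), clashes = c(2L, 2L),
                     hbonds = c(2L, 2L), stringsAsFactors = FALSE)
  expect_identical(pick_winner(tie2)$pose_id, "a")
  expect_identical(pick_winner(rec, eligible = rec$hbonds >= 4)$pose_id,
                   "p3")
  expect_identical(
    pick_winner(rec, eligible = function(r) r$clashes > 4)$pose_id, "p1")
  expect_error(pick_winner(rec[0, ]), "no eligible records")
})
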