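# Shared toy-structure builders and independent oracles used across the
# test files. Everything here is deliberately simple and self-contained so
# that it can serve as an independent check on the package internals.

## ---- atom-table / structure builders --------------------------------------

td_atom_table <- function(xyz, name = "C", element = "C", resname = "UNK",
                          chain = "A", resseq = NULL, type = "ATOM",
                          altloc = "", occupancy = 1,
                          polar_role = NA_character_) {
  xyz <- matrix(xyz, ncol = 3)
  n <- nrow(xyz)
  rep_n <- function(v) rep(v, length.out = n)
  data.frame(type = rep_n(type), serial = seq_len(n), name = rep_n(name),
             altloc = rep_n(altloc), resname = rep_n(resname),
             chain = rep_n(chain),
             resseq = if (is.null(resseq)) seq_len(n) else rep_n(resseq),
             insert = "", x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
             occupancy = rep_n(occupancy), bfactor = 0,
             element = rep_n(element), polar_role = rep_n(polar_role),
             stringsAsFactors = FALSE)
}

td_protein <- function(xyz, ..., id = "toy") {
  new_protein_structure(td_atom_table(xyz, ...), id = id)
}

## minimal pose object: the scoring/classification functions only need xyz,
## hydroxyl indices, ring indices, atom names and a pose id
td_pose <- function(xyz, hydroxyl = NULL, rings = NULL, names = NULL,
                    pose_id = "toy_pose") {
  xyz <- matrix(xyz, ncol = 3)
  if (is.null(names)) names <- sprintf("A%d", seq_len(nrow(xyz)))
  list(pose_id = pose_id, xyz = xyz, hydroxyl = hydroxyl, rings = rings,
       atoms = data.frame(name = names, element = "C",
                          stringsAsFactors = FALSE))
}

## apply a rigid transform to a whole ProteinStructure
td_transform_protein <- function(s, tr) {
  a <- s$atoms
  moved <- apply_transform(tr, as.matrix(a[, c("x", "y", "z")]))
  a$x <- moved[, 1]; a$y <- moved[, 2]; a$z <- moved[, 3]
  new_protein_structure(a, id = s$id)
}

td_random_rotation <- function() {
  q <- qr.Q(qr(matrix(rnorm(9), 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

## ---- symmetric / asymmetric toy ligand conformers -------------------------

## 7-atom two-ring toy with exact end-to-end symmetry: a pi rotation about z
## maps each atom onto its inversion partner, so an inverted self-fit has
## zero RMSD
td_symmetric_conformer <- function() {
  xyz <- rbind(c(-5, 0, 0),            # O1
               c(-4, 1, 0), c(-4, -1, 0),   # S1 S2 (epsilon)
               c(0, 0, 1),             # M1
               c(4, 1, 0), c(4, -1, 0),     # L1 L2 (beta)
               c(5, 0, 0))             # O2
  atoms <- data.frame(name = c("O1", "S1", "S2", "M1", "L1", "L2", "O2"),
                      element = c("O", "C", "C", "C", "C", "C", "O"),
                      x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
                      stringsAsFactors = FALSE)
  new_ligand_conformer(atoms, hydroxyl = c(1L, 7L),
                       rings = list(epsilon = 2:3, beta = 5:6),
                       inversion = c(7L, 6L, 5L, 4L, 3L, 2L, 1L),
                       source = list(structure_id = "toy", chain = "X",
                                     resseq = 1L))
}

## ---- hand-written PDB lines (fixed 80-column layout) ----------------------

td_pdb_line <- function(serial, name, resname, chain, resseq, x, y, z,
                        occ = 1, b = 0, element = "C", altloc = " ",
                        type = "ATOM") {
  sprintf("%-6s%5d %-4s%1s%-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          type, serial, name, altloc, resname, chain, resseq,
          x, y, z, occ, b, element)
}

## ---- brute-force rotation oracle for the Kabsch fit -----------------------

## minimal fitted RMSD over an Euler-angle grid (coarse pass then local
## refinement); independent of the SVD solution
td_brute_rmsd <- function(moving, target, coarse = 6, fine = 1) {
  P <- sweep(moving, 2, colMeans(moving))
  Q <- sweep(target, 2, colMeans(target))
  H <- crossprod(P, Q)
  n <- nrow(P)
  sp_sq <- sum(P^2) + sum(Q^2)
  rot <- function(a, b, c) {
    Rz <- function(t) matrix(c(cos(t), sin(t), 0, -sin(t), cos(t), 0,
                               0, 0, 1), 3)
    Ry <- function(t) matrix(c(cos(t), 0, -sin(t), 0, 1, 0,
                               sin(t), 0, cos(t)), 3)
    Rz(a) %*% Ry(b) %*% Rz(c)
  }
  best <- c(0, 0, 0); bestv <- -Inf
  search <- function(as, bs, cs) {
    for (a in as) for (b in bs) for (cc in cs) {
      v <- sum(rot(a, b, cc) * t(H))   # trace(R %*% H)
      if (v > bestv) { bestv <<- v; best <<- c(a, b, cc) }
    }
  }
  d2r <- pi / 180
  search(seq(0, 360 - coarse, by = coarse) * d2r,
         seq(0, 180, by = coarse) * d2r,
         seq(0, 360 - coarse, by = coarse) * d2r)
  span <- coarse * d2r
  search(seq(best[1] - span, best[1] + span, by = fine * d2r),
         seq(best[2] - span, best[2] + span, by = fine * d2r),
         seq(best[3] - span, best[3] + span, by = fine * d2r))
  sqrt(max(0, sp_sq - 2 * bestv) / n)
}

## ---- curved-tube cavity fixture -------------------------------------------

## an open-curved sealed tube whose centerline is a circular arc of radius
## Rc spanning angle phi in the xy plane; inner radius r. The geodesic
## tunnel length through it should be close to the arc length Rc * phi.
td_curved_tube <- function(Rc = 20, phi = 1.0, r = 3.0, ws = 1.2,
                           hole = 1.2) {
  rinf <- r + 1.70 + 1.4   # carbon vdW + probe
  pts <- list()
  for (t in seq(0, phi, by = ws / Rc)) {
    c0 <- c(Rc * sin(t), Rc * (1 - cos(t)), 0)
    n1 <- c(-sin(t), cos(t), 0)
    n2 <- c(0, 0, 1)
    nr <- max(8L, ceiling(2 * pi * rinf / ws))
    ang <- 2 * pi * (seq_len(nr) - 1) / nr + t
    pts[[length(pts) + 1L]] <- t(sapply(ang, function(a)
      c0 + rinf * (cos(a) * n1 + sin(a) * n2)))
  }
  ## end caps with holes narrower than the inflation radius, so the
  ## probe-inflated surface seals them
  cap_off <- sqrt((1.70 + 1.4)^2 - hole^2)
  for (tt in c(0, phi)) {
    c0 <- c(Rc * sin(tt), Rc * (1 - cos(tt)), 0)
    tang <- c(cos(tt), sin(tt), 0) * (if (tt == 0) -1 else 1)
    n1 <- c(-sin(tt), cos(tt), 0); n2 <- c(0, 0, 1)
    for (rr in seq(hole, rinf, by = ws)) {
      nr <- max(6L, ceiling(2 * pi * rr / ws))
      ang <- 2 * pi * (seq_len(nr) - 1) / nr
      pts[[length(pts) + 1L]] <- t(sapply(ang, function(a)
        c0 + cap_off * tang + rr * (cos(a) * n1 + sin(a) * n2)))
    }
  }
  xyz <- do.call(rbind, pts)
  prot <- td_protein(xyz, resname = "WAL", polar_role = "none",
                     id = "curved_tube")
  portals <- list(
    portal1 = portal_definition("portal1", c(0, 0, 0), c(-1, 0, 0)),
    portal2 = portal_definition("portal2",
                                c(Rc * sin(phi), Rc * (1 - cos(phi)), 0),
                                c(cos(phi), sin(phi), 0)))
  list(structure = prot, portals = portals, arc_length = Rc * phi)
}

## ---- random rigid pose generator over the synthetic tunnel ----------------

## random rigid placements of library conformers in and around the tunnel;
## used to compare the grid and exhaustive scoring paths
td_random_poses <- function(library, n, seed = 1) {
  set.seed(seed)
  lapply(seq_len(n), function(i) {
    conf <- library[[(i - 1L) %% length(library) + 1L]]
    xyz <- conformer_xyz(conf)
    R <- td_random_rotation()
    shift <- c(runif(1, -14, 14), runif(1, -6, 6), runif(1, -6, 6))
    moved <- sweep(xyz %*% t(R), 2, shift, "+")
    list(pose_id = sprintf("rnd_%04d", i), xyz = moved,
         hydroxyl = conf$hydroxyl, rings = conf$rings, atoms = conf$atoms)
  })
}
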