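# Structure I/O, altloc handling, ligand-conformer extraction, polar roles.

test_that("a minimal one-atom PDB parses with default occupancy", {
  path <- tempfile(fileext = ".pdb")
  writeLines(td_pdb_line(1, "CA", "ALA", "A", 1, 11.104, 6.134, 1.567),
             path)
  s <- read_structure(path)
  expect_s3_class(s, "ProteinStructure")
  expect_identical(nrow(s$atoms), 1L)
  expect_equal(s$atoms$occupancy, 1.0)
  expect_identical(s$atoms$name, "CA")
  expect_identical(s$atoms$element, "C")
  expect_equal(s$atoms$x, 11.104)
})

test_that("structures round-trip through write_structure / read_structure", {
  tun <- make_tunnel_protein(tunnel_spec())
  path <- tempfile(fileext = ".pdb")
  write_structure(tun$structure, path)
  back <- read_structure(path)
  a0 <- tun$structure$atoms
  a1 <- back$atoms
  expect_identical(nrow(a1), nrow(a0))
  expect_identical(a1$name, a0$name)
  expect_identical(a1$resname, a0$resname)
  expect_identical(a1$element, a0$element)
  expect_identical(a1$resseq, a0$resseq)
  expect_equal(a1$x, a0$x, tolerance = 1e-3)
  expect_equal(a1$y, a0$y, tolerance = 1e-3)
  expect_equal(a1$z, a0$z, tolerance = 1e-3)
})

test_that("malformed coordinate records are reported with their line number", {
  path <- tempfile(fileext = ".pdb")
  writeLines(c(td_pdb_line(1, "CA", "ALA", "A", 1, 1, 2, 3),
               "ATOM      2  CA  ALA A   2      bad",
               td_pdb_line(3, "CA", "ALA", "A", 3, 4, 5, 6)),
             path)
  expect_error(read_structure(path), "line 2")
  path2 <- tempfile(fileext = ".pdb")
  bad <- td_pdb_line(1, "CA", "ALA", "A", 1, 1, 2, 3)
  substr(bad, 31, 38) <- "  xx.yyy"
  writeLines(c(td_pdb_line(1, "CA", "ALA", "A", 1, 1, 2, 3), bad), path2)
  expect_error(read_structure(path2), "line 2.*non-numeric")
})

test_that("unknown element symbols are rejected", {
  path <- tempfile(fileext = ".pdb")
  writeLines(td_pdb_line(1, "Q1", "UNK", "A", 1, 0, 0, 0, element = "Q"),
             path)
  expect_error(read_structure(path), "unknown element")
})

test_that("missing files and empty structures error", {
  expect_error(read_structure(tempfile(fileext = ".pdb")), "file not found")
  s <- td_protein(c(0, 0, 0))
  s$atoms <- s$atoms[0, , drop = FALSE]
  expect_error(write_structure(s, tempfile(fileext = ".pdb")),
               "no atoms")
})

test_that("the atom table constructor validates its input", {
  expect_error(new_protein_structure(data.frame(x = 1)),
               "lacks columns")
  a <- td_atom_table(c(0, 0, 0))
  a$x <- NA_real_
  expect_error(new_protein_structure(a), "non-finite")
  b <- td_atom_table(c(0, 0, 0), occupancy = 1.5)
  expect_error(new_protein_structure(b), "occupancies")
})

test_that("docking_atoms drops hydrogens, waters and additives", {
  xyz <- matrix(rnorm(18), ncol = 3)
  a <- td_atom_table(xyz,
                     name = c("CA", "H1", "O", "O1", "CB", "S"),
                     element = c("C", "H", "O", "O", "C", "S"),
                     resname = c("ALA", "ALA", "HOH", "EDO", "GLY", "MET"))
  s <- new_protein_structure(a)
  d <- docking_atoms(s)
  expect_identical(d$atoms$name, c("CA", "CB", "S"))
  d2 <- docking_atoms(s, include_solvent = TRUE)
  expect_identical(d2$atoms$name, c("CA", "O", "O1", "CB", "S"))
})

test_that("altloc occupancy sums above one trigger a warning on read", {
  path <- tempfile(fileext = ".pdb")
  writeLines(c(td_pdb_line(1, "CB", "ALA", "A", 1, 0, 0, 0, occ = 0.7,
                           altloc = "A"),
               td_pdb_line(2, "CB", "ALA", "A", 1, 2, 0, 0, occ = 0.7,
                           altloc = "B")),
             path)
  expect_warning(read_structure(path), "occupancies sum to > 1")
})

test_that("collapse_altlocs keeps the highest occupancy, ties break to 'A'", {
  a <- td_atom_table(matrix(rnorm(12), ncol = 3),
                     name = c("CB", "CB", "CG", "CG"),
                     resseq = c(1, 1, 2, 2),
                     altloc = c("A", "B", "A", "B"),
                     occupancy = c(0.4, 0.6, 0.5, 0.5))
  s <- collapse_altlocs(new_protein_structure(a))
  expect_identical(nrow(s$atoms), 2L)
  expect_identical(s$atoms$altloc[s$atoms$name == "CB"], "B")
  expect_identical(s$atoms$altloc[s$atoms$name == "CG"], "A")
})

test_that("select_model applies altloc choices, deletions and truncations", {
  nm <- c("N", "CA", "C", "O", "CB", "CG", "CG")
  a <- td_atom_table(matrix(seq_len(21), ncol = 3),
                     name = nm, resname = "GLU",
                     resseq = c(10, 10, 10, 10, 10, 10, 10),
                     altloc = c("", "", "", "", "", "A", "B"),
                     occupancy = c(1, 1, 1, 1, 1, 0.5, 0.5))
  b <- td_atom_table(matrix(rnorm(9), ncol = 3),
                     name = c("N", "CA", "C"), resname = "GLY", resseq = 11)
  s <- new_protein_structure(rbind(a, b))
  grp <- list(omega = list(chain = "A", resseq = 10),
              tail = list(chain = "A", resseq = 11))

  m1 <- conformer_model(grp, choices = c(omega = "B"))
  r1 <- select_model(s, m1)
  kept <- r1$atoms[r1$atoms$resseq == 10, ]
  expect_identical(sum(kept$name == "CG"), 1L)
  expect_identical(kept$altloc[kept$name == "CG"], "B")
  ## no duplicated (chain, resseq, name) among altloc-resolved atoms
  expect_false(anyDuplicated(kept[, c("chain", "resseq", "name")]) > 0)

  m2 <- conformer_model(grp, delete = "tail")
  r2 <- select_model(s, m2)
  expect_false(any(r2$atoms$resseq == 11))

  m3 <- conformer_model(grp, truncate_to_alanine = "omega")
  r3 <- select_model(s, m3)
  expect_identical(sort(r3$atoms$name[r3$atoms$resseq == 10]),
                   sort(c("N", "CA", "C", "O", "CB")))

  expect_error(select_model(s, conformer_model(grp, choices = c(omega = "C"))),
               "altloc 'C' not present.*available: A, B")
  expect_error(conformer_model(grp, delete = "nope"),
               "undefined group")
  m4 <- conformer_model(list(ghost = list(chain = "A", resseq = 999)))
  expect_error(select_model(s, m4), "resolves to no atoms")
})

test_that("ligand conformers are extracted per instance in dictionary order", {
  register_ligand_species(
    "TOY",
    heavy_atoms = c("O1", "S1", "S2", "M1", "L1", "L2", "O2"),
    hydroxyl = c("O1", "O2"),
    rings = list(beta = c("L1", "L2"), epsilon = c("S1", "S2")),
    inversion = c(O1 = "O2", S1 = "L2", S2 = "L1"))
  conf <- td_symmetric_conformer()
  xyz <- conformer_xyz(conf)
  mk <- function(resseq, order, drop = integer(0)) {
    keep <- setdiff(order, drop)
    td_atom_table(xyz[keep, , drop = FALSE],
                  name = conf$atoms$name[keep],
                  element = conf$atoms$element[keep],
                  resname = "TOY", chain = "X", resseq = resseq,
                  type = "HETATM")
  }
  a <- rbind(mk(1, 1:7),
             mk(2, c(4, 7, 1, 2, 6, 5, 3)),  # scrambled file order
             mk(3, 1:7, drop = 5L))           # L1 missing: incomplete
  a$serial <- seq_len(nrow(a))
  path <- tempfile(fileext = ".pdb")
  write_structure(new_protein_structure(a, id = "toyfile"), path)

  expect_message(confs <- extract_ligand_conformers(path, "TOY"),
                 "1 incomplete conformer")
  expect_length(confs, 2L)
  expect_identical(attr(confs, "n_excluded"), 1L)
  for (cc in confs) {
    expect_identical(cc$atoms$name,
                     c("O1", "S1", "S2", "M1", "L1", "L2", "O2"))
    expect_identical(cc$inversion[cc$inversion], seq_len(7L))
    expect_identical(cc$hydroxyl, c(1L, 7L))
  }
  ## the scrambled instance is re-ordered to canonical coordinates
  expect_equal(conformer_xyz(confs[[2]]), xyz, tolerance = 1e-3,
               ignore_attr = TRUE)

  expect_error(extract_ligand_conformers(path, "LUT"),
               "no instance of residue 'LUT'")
})

test_that("the ligand dictionary validates entries and ships a LUT record", {
  lut <- ligand_dictionary("LUT")
  expect_true(all(c("heavy_atoms", "hydroxyl", "rings", "inversion_full")
                  %in% names(lut)))
  expect_length(lut$hydroxyl, 2L)
  expect_true(all(c("beta", "epsilon") %in% names(lut$rings)))
  ## the completed inversion map is a name-level involution
  inv <- lut$inversion_full
  expect_identical(unname(inv[unname(inv)]), names(inv))
  expect_error(ligand_dictionary("ZZZ"), "no dictionary entry")
  expect_error(register_ligand_species("BAD", heavy_atoms = c("O1", "O2"),
                                       hydroxyl = "O1",
                                       rings = list(beta = "O1",
                                                    epsilon = "O2"),
                                       inversion = c(O1 = "O2")),
               "exactly 2 hydroxyl")
})

test_that("new_ligand_conformer rejects non-involutive inversion maps", {
  conf <- td_symmetric_conformer()
  expect_error(new_ligand_conformer(conf$atoms, conf$hydroxyl, conf$rings,
                                    inversion = c(2L, 3L, 1L, 4:7),
                                    source = conf$source),
               "not an involution")
})

test_that("hydroxyl_span is the terminal O-O distance, rigid-invariant", {
  conf <- td_symmetric_conformer()
  conf$atoms$x[c(1, 7)] <- c(0, 3)
  conf$atoms$y[c(1, 7)] <- c(0, 4)
  conf$atoms$z[c(1, 7)] <- c(0, 0)
  expect_equal(hydroxyl_span(conf), 5.0)
  set.seed(4)
  tr <- rigid_transform(td_random_rotation(), rnorm(3, 0, 10))
  moved <- conf
  xyz <- apply_transform(tr, conformer_xyz(conf))
  moved$atoms$x <- xyz[, 1]; moved$atoms$y <- xyz[, 2]
  moved$atoms$z <- xyz[, 3]
  expect_equal(hydroxyl_span(moved), hydroxyl_span(conf), tolerance = 1e-9)
})

test_that("polar roles follow the residue dictionary", {
  nms <- c("N", "O", "CB", "N", "OG", "OD1", "ND2", "O", "N")
  res <- c("ALA", "ALA", "ALA", "PRO", "SER", "ASP", "ASN", "HOH", "XYZ")
  ele <- c("N", "O", "C", "N", "O", "O", "N", "O", "N")
  s <- new_protein_structure(
    td_atom_table(matrix(seq_len(27), ncol = 3), name = nms,
                  resname = res, element = ele, resseq = 1:9))
  expect_warning(s2 <- assign_polar_roles(s), "unrecognised residue.*XYZ")
  role <- s2$atoms$polar_role
  expect_identical(role, c("donor", "acceptor", "none", "none", "both",
                           "acceptor", "donor", "both", "none"))
})

test_that("assign_polar_roles keeps pre-set roles by default", {
  s <- td_protein(matrix(c(0, 0, 0, 1, 0, 0), ncol = 3, byrow = TRUE),
                  name = c("N", "O"), element = c("N", "O"),
                  resname = "ALA", resseq = c(1, 1))
  s$atoms$polar_role <- c("acceptor", NA)
  s2 <- assign_polar_roles(s)
  expect_identical(s2$atoms$polar_role, c("acceptor", "acceptor"))
  s3 <- assign_polar_roles(s, keep_existing = FALSE)
  expect_identical(s3$atoms$polar_role, c("donor", "acceptor"))
})
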