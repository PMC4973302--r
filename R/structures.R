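# Macromolecular coordinate handling: reading/writing PDB (and mmCIF) files,
# alternate-conformation (altloc) models, ligand-conformer extraction and
# donor/acceptor role assignment. Parsing itself is delegated to bio3d; this
# module owns the atom-table representation used by the rest of the package.

SOLVENT_RESNAMES  <- c("HOH", "WAT", "DOD", "SOL")
ADDITIVE_RESNAMES <- c("EDO", "GOL", "SO4", "TLA", "PEG", "PO4")
STANDARD_AA <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY",
                 "HIS", "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER",
                 "THR", "TRP", "TYR", "VAL")
KNOWN_ELEMENTS <- c("H", "D", "C", "N", "O", "S", "P", "SE", "F", "CL",
                    "BR", "I", "NA", "K", "MG", "CA", "ZN", "FE", "MN", "CU")

#' Construct a ProteinStructure from an atom table
#'
#' Validates the atom data frame (required columns, finite coordinates,
#' occupancies in `[0, 1]`) and wraps it. Columns: `type` (`ATOM`/`HETATM`),
#' `serial`, `name`, `altloc`, `resname`, `chain`, `resseq`, `insert`,
#' `x`, `y`, `z`, `occupancy`, `bfactor`, `element`, `polar_role`.
#'
#' @param atoms Atom data frame with the columns listed above.
#' @param id Structure identifier string.
#' @return A `ProteinStructure`.
#' @export
new_protein_structure <- function(atoms, id = "structure") {
  stopifnot(is.data.frame(atoms))
  req <- c("type", "serial", "name", "altloc", "resname", "chain", "resseq",
           "insert", "x", "y", "z", "occupancy", "bfactor", "element",
           "polar_role")
  miss <- setdiff(req, names(atoms))
  if (length(miss) > 0) stop("atom table lacks columns: ", paste(miss, collapse = ", "))
  if (any(!is.finite(as.matrix(atoms[, c("x", "y", "z")]))))
    stop("non-finite atom coordinates")
  if (any(atoms$occupancy < 0 | atoms$occupancy > 1))
    stop("occupancies must lie in [0, 1]")
  rownames(atoms) <- NULL
  structure(list(atoms = atoms, id = id), class = "ProteinStructure")
}

#' @export
print.ProteinStructure <- function(x, ...) {
  a <- x$atoms
  nres <- nrow(unique(a[, c("chain", "resseq", "insert")]))
  cat("ProteinStructure '", x$id, "': ", nrow(a), " atoms, ",
      nres, " residues, ", sum(a$altloc != ""), " altloc atoms\n", sep = "")
  invisible(x)
}

#' Atom coordinates as a matrix
#'
#' @param s A `ProteinStructure`.
#' @return Numeric n x 3 matrix of coordinates (angstrom).
#' @export
atom_xyz <- function(s) {
  as.matrix(s$atoms[, c("x", "y", "z")])
}

## Check fixed-width coordinate fields of raw PDB lines before parsing, so
## that malformed records are reported with their line number.
validate_pdb_lines <- function(path) {
  lines <- readLines(path, warn = FALSE)
  rec <- substr(lines, 1, 6)
  idx <- which(rec %in% c("ATOM  ", "HETATM"))
  for (i in idx) {
    ln <- lines[i]
    if (nchar(ln) < 54)
      stop("unparseable record at line ", i, " of ", path, ": too short")
    coords <- suppressWarnings(as.numeric(c(substr(ln, 31, 38),
                                            substr(ln, 39, 46),
                                            substr(ln, 47, 54))))
    if (any(is.na(coords)))
      stop("unparseable record at line ", i, " of ", path,
           ": non-numeric coordinate field")
  }
  invisible(length(idx))
}

element_from_name <- function(elety) {
  # strip digits/primes, take leading alphabetic; two-letter elements appear
  # with their full symbol in the name (e.g. SE, FE in HETATM records)
  nm <- gsub("[^A-Za-z]", "", elety)
  two <- toupper(substr(nm, 1, 2))
  one <- toupper(substr(nm, 1, 1))
  ifelse(two %in% c("SE", "CL", "BR", "MG", "ZN", "FE", "MN", "CU", "NA2"),
         two, one)
}

bio3d_to_atoms <- function(pdb) {
  a <- pdb$atom
  element <- toupper(trimws(a$elesy %||% ""))
  element[is.na(element) | element == ""] <-
    element_from_name(a$elety[is.na(element) | element == ""])
  bad <- !(element %in% KNOWN_ELEMENTS)
  if (any(bad))
    stop("unknown element(s): ",
         paste(unique(element[bad]), collapse = ", "))
  alt <- a$alt
  alt[is.na(alt)] <- ""
  ins <- a$insert
  ins[is.na(ins)] <- ""
  occ <- a$o
  occ[is.na(occ)] <- 1.0
  b <- a$b
  b[is.na(b)] <- 0.0
  data.frame(type = a$type, serial = a$eleno, name = trimws(a$elety),
             altloc = alt, resname = trimws(a$resid), chain = a$chain,
             resseq = a$resno, insert = ins,
             x = a$x, y = a$y, z = a$z,
             occupancy = occ, bfactor = b, element = element,
             polar_role = NA_character_,
             stringsAsFactors = FALSE)
}

check_altloc_occupancies <- function(atoms, id) {
  withalt <- atoms[atoms$altloc != "", , drop = FALSE]
  if (nrow(withalt) == 0) return(invisible(TRUE))
  key <- paste(withalt$chain, withalt$resseq, withalt$insert, withalt$name)
  sums <- tapply(withalt$occupancy, key, sum)
  if (any(sums > 1.001))
    warning("structure '", id, "': altloc occupancies sum to > 1 for ",
            sum(sums > 1.001), " atom group(s)")
  invisible(TRUE)
}

#' Read a macromolecular structure
#'
#' Parses all ATOM/HETATM records of a PDB (or mmCIF) file into an atom
#' table, preserving altloc labels, occupancies and insertion codes.
#'
#' @param path Path to the coordinate file.
#' @param dialect `"pdb"` (default) or `"mmcif"`.
#' @param id Structure identifier; defaults to the file name without
#'   extension.
#' @return A `ProteinStructure`.
#' @export
read_structure <- function(path, dialect = c("pdb", "mmcif"), id = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  id <- id %||% sub("\\.[^.]*$", "", basename(path))
  pdb <- if (dialect == "pdb") {
    validate_pdb_lines(path)
    bio3d::read.pdb(path, multi = FALSE, rm.insert = FALSE, rm.alt = FALSE,
                    verbose = FALSE)
  } else {
    bio3d::read.cif(path, multi = FALSE, rm.insert = FALSE, rm.alt = FALSE,
                    verbose = FALSE)
  }
  atoms <- bio3d_to_atoms(pdb)
  check_altloc_occupancies(atoms, id)
  new_protein_structure(atoms, id = id)
}

#' Write a structure to a PDB file
#'
#' @param s A `ProteinStructure`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_structure <- function(s, path) {
  a <- s$atoms
  if (nrow(a) == 0) stop("refusing to write a structure with no atoms")
  bio3d::write.pdb(file = path,
                   type = a$type,
                   xyz = as.vector(t(as.matrix(a[, c("x", "y", "z")]))),
                   resno = a$resseq, resid = a$resname, eleno = a$serial,
                   elety = a$name, chain = a$chain,
                   insert = ifelse(a$insert == "", NA, a$insert),
                   alt = ifelse(a$altloc == "", NA, a$altloc),
                   o = a$occupancy, b = a$bfactor, elesy = a$element)
  invisible(path)
}

#' Protein atom subset used for docking scores
#'
#' Heavy protein atoms, excluding waters and crystallisation additives by
#' default (the ligand is docked into the solvent-occupied cavity).
#'
#' @param s A `ProteinStructure`.
#' @param include_solvent Keep waters and additives (default `FALSE`).
#' @return A `ProteinStructure` restricted to the docking atom set.
#' @export
docking_atoms <- function(s, include_solvent = FALSE) {
  a <- s$atoms
  keep <- !(a$element %in% c("H", "D"))
  if (!include_solvent)
    keep <- keep & !(a$resname %in% c(SOLVENT_RESNAMES, ADDITIVE_RESNAMES))
  new_protein_structure(a[keep, , drop = FALSE], id = s$id)
}

## ----- alternate-conformation models ---------------------------------------

#' Describe a single-conformer protein model
#'
#' A conformer model names groups of residues (by chain and residue numbers),
#' picks one altloc per group, and optionally deletes a group or truncates
#' its residues to alanine (keeping N, CA, C, O, CB only).
#'
#' @param groups Named list; each element is `list(chain =, resseq =)`.
#' @param choices Named character vector: group name -> altloc to keep.
#' @param delete Character vector of group names to remove entirely.
#' @param truncate_to_alanine Character vector of group names whose residues
#'   are reduced to their alanine atom set.
#' @return A `ConformerModel`.
#' @export
conformer_model <- function(groups, choices = character(),
                            delete = character(),
                            truncate_to_alanine = character()) {
  named <- unique(c(names(choices), delete, truncate_to_alanine))
  unknown <- setdiff(named, names(groups))
  if (length(unknown) > 0)
    stop("conformer model refers to undefined group(s): ",
         paste(unknown, collapse = ", "))
  structure(list(groups = groups, choices = choices, delete = delete,
                 truncate_to_alanine = truncate_to_alanine),
            class = "ConformerModel")
}

group_rows <- function(atoms, g) {
  sel <- atoms$resseq %in% g$resseq
  if (!is.null(g$chain)) sel <- sel & atoms$chain %in% g$chain
  which(sel)
}

#' Apply a conformer model to a structure
#'
#' Retains exactly one altloc for each group with an altloc choice, then
#' applies deletions and alanine truncations. Atoms outside the named groups
#' are untouched.
#'
#' @param s A `ProteinStructure`.
#' @param m A `ConformerModel`.
#' @return The reduced `ProteinStructure`.
#' @export
select_model <- function(s, m) {
  stopifnot(inherits(m, "ConformerModel"))
  atoms <- s$atoms
  for (gname in names(m$groups)) {
    if (length(group_rows(atoms, m$groups[[gname]])) == 0)
      stop("group '", gname, "' resolves to no atoms in structure '", s$id, "'")
  }
  drop <- rep(FALSE, nrow(atoms))
  for (gname in names(m$choices)) {
    rows <- group_rows(atoms, m$groups[[gname]])
    alts <- setdiff(unique(atoms$altloc[rows]), "")
    want <- m$choices[[gname]]
    if (!want %in% alts)
      stop("altloc '", want, "' not present for group '", gname,
           "'; available: ", paste(alts, collapse = ", "))
    drop[rows[atoms$altloc[rows] != "" & atoms$altloc[rows] != want]] <- TRUE
  }
  for (gname in m$delete) {
    drop[group_rows(atoms, m$groups[[gname]])] <- TRUE
  }
  for (gname in m$truncate_to_alanine) {
    rows <- group_rows(atoms, m$groups[[gname]])
    keepnames <- c("N", "CA", "C", "O", "CB")
    drop[rows[!atoms$name[rows] %in% keepnames]] <- TRUE
  }
  new_protein_structure(atoms[!drop, , drop = FALSE], id = s$id)
}

#' Collapse remaining altloc groups to a single conformer
#'
#' Keeps the highest-occupancy altloc for every residual
#' alternate-conformation atom group; ties break toward the alphabetically
#' first altloc label ('A' before 'B').
#'
#' @param s A `ProteinStructure`.
#' @return Single-conformer `ProteinStructure`.
#' @export
collapse_altlocs <- function(s) {
  a <- s$atoms
  withalt <- which(a$altloc != "")
  if (length(withalt) == 0) return(s)
  key <- paste(a$chain[withalt], a$resseq[withalt], a$insert[withalt],
               a$name[withalt], sep = "|")
  keep <- rep(TRUE, nrow(a))
  for (k in unique(key)) {
    rows <- withalt[key == k]
    if (length(rows) == 1) next
    ord <- order(-a$occupancy[rows], a$altloc[rows])
    keep[rows[ord[-1]]] <- FALSE
  }
  new_protein_structure(a[keep, , drop = FALSE], id = s$id)
}

## ----- ligand conformers ----------------------------------------------------

#' Construct a LigandConformer
#'
#' Validates that the inversion map is an involution and that exactly two
#' hydroxyl oxygens are referenced, then wraps the pieces.
#'
#' @param atoms Data frame with at least `name`, `element`, `x`, `y`, `z`.
#' @param hydroxyl Integer indices of the two terminal hydroxyl oxygens.
#' @param rings List with integer index vectors `beta` and `epsilon`.
#' @param inversion Integer permutation exchanging the two molecular ends.
#' @param source List with `structure_id`, `chain`, `resseq`.
#' @return A `LigandConformer`.
#' @export
new_ligand_conformer <- function(atoms, hydroxyl, rings, inversion, source) {
  n <- nrow(atoms)
  stopifnot(length(hydroxyl) == 2, all(hydroxyl >= 1 & hydroxyl <= n))
  if (!identical(inversion[inversion], seq_len(n)))
    stop("inversion map is not an involution")
  structure(list(atoms = atoms, hydroxyl = hydroxyl, rings = rings,
                 inversion = inversion, source = source),
            class = "LigandConformer")
}

#' @export
print.LigandConformer <- function(x, ...) {
  cat("LigandConformer: ", nrow(x$atoms), " heavy atoms, hydroxyl span ",
      sprintf("%.2f", hydroxyl_span(x)), " A (source: ",
      paste(unlist(x$source), collapse = "/"), ")\n", sep = "")
  invisible(x)
}

#' Ligand conformer coordinates as a matrix
#' @param c A `LigandConformer`.
#' @return Numeric n x 3 coordinate matrix.
#' @export
conformer_xyz <- function(c) {
  as.matrix(c$atoms[, c("x", "y", "z")])
}

conformer_from_atoms <- function(atoms, dict, source) {
  # atoms: rows of one residue instance (heavy atoms, altlocs collapsed)
  ord <- match(dict$heavy_atoms, atoms$name)
  if (any(is.na(ord))) return(NULL)  # incomplete: caller counts the exclusion
  atoms <- atoms[ord, , drop = FALSE]
  rownames(atoms) <- NULL
  nm <- atoms$name
  inv_named <- dict$inversion_full
  inversion <- seq_along(nm)
  mapped <- nm %in% names(inv_named)
  inversion[mapped] <- match(inv_named[nm[mapped]], nm)
  hydroxyl <- match(dict$hydroxyl, nm)
  rings <- list(beta = match(dict$rings$beta, nm),
                epsilon = match(dict$rings$epsilon, nm))
  new_ligand_conformer(atoms, hydroxyl, rings, inversion, source)
}

#' Extract ligand conformers from coordinate files
#'
#' Collects every instance of a named residue across the input files and
#' turns each complete instance into an annotated `LigandConformer`
#' (hydroxyl oxygens, ring memberships and end-to-end inversion map come
#' from the chemical dictionary). Instances with missing heavy atoms are
#' excluded and counted.
#'
#' @param paths Character vector of coordinate file paths.
#' @param residue_name Residue code of the ligand (e.g. `"LUT"`).
#' @param dialect Passed to [read_structure()].
#' @return List of `LigandConformer`; attribute `n_excluded` holds the
#'   number of incomplete instances dropped.
#' @export
extract_ligand_conformers <- function(paths, residue_name, dialect = "pdb") {
  dict <- ligand_dictionary(residue_name)
  out <- list()
  n_excluded <- 0L
  for (p in paths) {
    s <- read_structure(p, dialect = dialect)
    s <- collapse_altlocs(s)
    a <- s$atoms
    hit <- a$resname == residue_name & !(a$element %in% c("H", "D"))
    if (!any(hit)) next
    sub <- a[hit, , drop = FALSE]
    key <- paste(sub$chain, sub$resseq, sub$insert, sep = "|")
    for (k in unique(key)) {
      inst <- sub[key == k, , drop = FALSE]
      src <- list(structure_id = s$id, chain = inst$chain[1],
                  resseq = inst$resseq[1])
      conf <- conformer_from_atoms(inst, dict, src)
      if (is.null(conf)) n_excluded <- n_excluded + 1L
      else out[[length(out) + 1L]] <- conf
    }
  }
  if (length(out) == 0 && n_excluded == 0)
    stop("no instance of residue '", residue_name, "' found in the input files")
  if (n_excluded > 0)
    message(n_excluded, " incomplete conformer(s) of ", residue_name,
            " excluded")
  attr(out, "n_excluded") <- n_excluded
  out
}

#' Distance between the two terminal hydroxyl oxygens
#'
#' @param c A `LigandConformer`.
#' @return Euclidean distance in angstrom.
#' @export
hydroxyl_span <- function(c) {
  xyz <- conformer_xyz(c)
  vec_norm(xyz[c$hydroxyl[1], ] - xyz[c$hydroxyl[2], ])
}

## ----- polar roles ----------------------------------------------------------

SIDECHAIN_ROLES <- list(
  SER = c(OG = "both"), THR = c(OG1 = "both"), TYR = c(OH = "both"),
  ASP = c(OD1 = "acceptor", OD2 = "acceptor"),
  GLU = c(OE1 = "acceptor", OE2 = "acceptor"),
  ASN = c(OD1 = "acceptor", ND2 = "donor"),
  GLN = c(OE1 = "acceptor", NE2 = "donor"),
  ARG = c(NE = "donor", NH1 = "donor", NH2 = "donor"),
  LYS = c(NZ = "donor"),
  HIS = c(ND1 = "both", NE2 = "both"),
  TRP = c(NE1 = "donor"),
  EDO = c(O1 = "both", O2 = "both"),
  GOL = c(O1 = "both", O2 = "both", O3 = "both")
)

#' Assign hydrogen-bond donor/acceptor roles to protein atoms
#'
#' Tags every N and O atom with a role from a fixed residue dictionary:
#' backbone amide N = donor (none for proline), backbone carbonyl O (and
#' OXT) = acceptor, side chains per canonical chemistry, water O = both.
#' Carbon and sulfur atoms are `none`. Atoms of unrecognised residues are
#' tagged `none` with a single warning.
#'
#' @param s A `ProteinStructure`.
#' @param keep_existing Do not overwrite roles that are already set.
#' @return The structure with the `polar_role` column filled.
#' @export
assign_polar_roles <- function(s, keep_existing = TRUE) {
  a <- s$atoms
  role <- rep("none", nrow(a))
  isNO <- a$element %in% c("N", "O")
  std <- a$resname %in% STANDARD_AA
  # backbone
  role[std & a$name == "N" & a$resname != "PRO"] <- "donor"
  role[std & a$name %in% c("O", "OXT")] <- "acceptor"
  # side chains and small-molecule entries
  for (res in names(SIDECHAIN_ROLES)) {
    map <- SIDECHAIN_ROLES[[res]]
    rows <- which(a$resname == res & a$name %in% names(map))
    role[rows] <- map[a$name[rows]]
  }
  role[a$resname %in% SOLVENT_RESNAMES & a$element == "O"] <- "both"
  unknown <- isNO & !std &
    !(a$resname %in% c(SOLVENT_RESNAMES, names(SIDECHAIN_ROLES)))
  if (keep_existing) unknown <- unknown & is.na(a$polar_role)
  if (any(unknown))
    warning("polar roles defaulted to 'none' for unrecognised residue(s): ",
            paste(unique(a$resname[unknown]), collapse = ", "))
  role[!isNO] <- "none"
  if (keep_existing) {
    set <- is.na(a$polar_role)
    a$polar_role[set] <- role[set]
  } else {
    a$polar_role <- role
  }
  new_protein_structure(a, id = s$id)
}
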