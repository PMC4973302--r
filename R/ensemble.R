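# Docked-pose ensemble construction: every library conformer is superposed
# onto every template in the requested orientations (direct and end-to-end
# inverted), yielding provenance-tagged rigid poses. No structural
# adjustment beyond rotation and translation is ever applied.

new_pose <- function(conformer, template_idx, conformer_idx, orientation,
                     transform, xyz) {
  structure(list(
    pose_id = sprintf("t%03d_c%03d_%s", template_idx, conformer_idx,
                      orientation),
    template = template_idx, conformer = conformer_idx,
    orientation = orientation, transform = transform, xyz = xyz,
    atoms = conformer$atoms, hydroxyl = conformer$hydroxyl,
    rings = conformer$rings, inversion = conformer$inversion),
    class = "Pose")
}

#' Build the docked pose ensemble
#'
#' One pose per (template x conformer x orientation) combination: the
#' conformer is least-squares-fitted onto the template under the direct or
#' the end-to-end inverted atom correspondence, and all of its atoms are
#' carried along rigidly. Ordering is lexicographic in (template, conformer,
#' orientation) and the generation manifest allows exact regeneration.
#'
#' @param templates List of placed conformers (`LigandConformer`s whose
#'   coordinates are already in the protein frame).
#' @param library List of `LigandConformer`s to dock.
#' @param orientations Subset of `c("direct", "inverted")`.
#' @return A `PoseSet`.
#' @export
build_ensemble <- function(templates, library,
                           orientations = c("direct", "inverted")) {
  if (length(templates) == 0) stop("no templates supplied")
  if (length(library) == 0) stop("empty conformer library")
  orientations <- match.arg(orientations, several.ok = TRUE)
  poses <- vector("list", length(templates) * length(library) *
                    length(orientations))
  k <- 0L
  for (ti in seq_along(templates)) {
    txyz <- conformer_xyz(templates[[ti]])
    for (ci in seq_along(library)) {
      conf <- library[[ci]]
      cxyz <- conformer_xyz(conf)
      if (nrow(cxyz) != nrow(txyz))
        stop("conformer ", ci, " and template ", ti,
             " differ in atom count; same chemical species required")
      for (o in orientations) {
        corr <- if (o == "direct") direct_correspondence(nrow(cxyz))
                else inverted_correspondence(conf)
        fit <- kabsch_fit(cxyz, txyz, corr)
        placed <- apply_transform(fit$transform, cxyz)
        k <- k + 1L
        poses[[k]] <- new_pose(conf, ti, ci, o, fit$transform, placed)
      }
    }
  }
  poses <- poses[seq_len(k)]
  manifest <- list(
    n_templates = length(templates), n_conformers = length(library),
    orientations = orientations,
    template_md5 = object_md5(lapply(templates, conformer_xyz)),
    library_md5 = object_md5(lapply(library, conformer_xyz)),
    package_version = as.character(utils::packageVersion("tunneldock")))
  structure(list(poses = poses, manifest = manifest), class = "PoseSet")
}

#' @export
print.PoseSet <- function(x, ...) {
  m <- x$manifest
  cat("PoseSet: ", length(x$poses), " poses (",
      m$n_templates, " templates x ", m$n_conformers, " conformers x {",
      paste(m$orientations, collapse = ", "), "})\n", sep = "")
  invisible(x)
}

#' Write a protein-plus-pose complex to a PDB file
#'
#' The ligand pose is appended as a HETATM block on its own chain.
#'
#' @param p A `Pose`.
#' @param protein A `ProteinStructure`.
#' @param path Output file path.
#' @param ligand_chain Chain identifier for the ligand block.
#' @param ligand_resname Residue name for the ligand block.
#' @return `path`, invisibly.
#' @export
write_pose <- function(p, protein, path, ligand_chain = "X",
                       ligand_resname = "LIG") {
  if (is.null(p$xyz) || nrow(p$xyz) == 0) stop("pose has no ligand atoms")
  prot <- protein$atoms
  lig <- data.frame(
    type = "HETATM", serial = max(prot$serial) + seq_len(nrow(p$xyz)),
    name = p$atoms$name, altloc = "", resname = ligand_resname,
    chain = ligand_chain, resseq = 1L, insert = "",
    x = p$xyz[, 1], y = p$xyz[, 2], z = p$xyz[, 3],
    occupancy = 1.0, bfactor = 0.0, element = p$atoms$element,
    polar_role = NA_character_, stringsAsFactors = FALSE)
  combined <- new_protein_structure(rbind(prot, lig),
                                    id = paste0(protein$id, "+", p$pose_id))
  write_structure(combined, path)
}
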