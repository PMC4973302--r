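# Pose classification: portal penetration (which cavity openings the rigid
# ligand breaches) and terminal-ring orientation (epsilon ring buried toward
# the small portal versus the beta ring buried).

#' Construct a portal definition
#'
#' A portal is modelled as a flat gate plane: a gate point with an outward
#' unit normal. A ligand atom with positive signed distance along the normal
#' lies beyond the gate.
#'
#' @param label `"portal1"` (larger opening) or `"portal2"` (smaller).
#' @param gate_point Length-3 point on the gate plane.
#' @param normal Outward plane normal (normalised internally).
#' @param residues Optional residue selection the plane was derived from.
#' @param aperture Optional `c(width, height)` in angstrom.
#' @return A `PortalDefinition`.
#' @export
portal_definition <- function(label, gate_point, normal, residues = NULL,
                              aperture = NULL) {
  stopifnot(label %in% c("portal1", "portal2"),
            length(gate_point) == 3, length(normal) == 3)
  structure(list(label = label, gate_point = as.numeric(gate_point),
                 normal = unit_vec(normal), residues = residues,
                 aperture = aperture),
            class = "PortalDefinition")
}

#' Derive the two portal gate planes from lining residues
#'
#' Each gate point is the centroid of the lining-residue atoms; the outward
#' normal points away from the cavity centre (by default the centroid of the
#' docking atom set).
#'
#' @param protein A `ProteinStructure`.
#' @param portal1,portal2 Residue selections `list(chain =, resseq =)` for
#'   the two portals.
#' @param center Optional cavity centre; defaults to the protein centroid.
#' @return List with elements `portal1` and `portal2`.
#' @export
define_portals <- function(protein, portal1, portal2, center = NULL) {
  a <- protein$atoms
  center <- center %||% colMeans(atom_xyz(docking_atoms(protein)))
  gate_of <- function(sel, label) {
    rows <- group_rows(a, sel)
    missing <- setdiff(sel$resseq, unique(a$resseq[rows]))
    if (length(missing) > 0)
      stop(label, ": residues not found: ", paste(missing, collapse = ", "))
    gp <- colMeans(as.matrix(a[rows, c("x", "y", "z")]))
    portal_definition(label, gp, gp - center, residues = sel)
  }
  p1 <- gate_of(portal1, "portal1")
  p2 <- gate_of(portal2, "portal2")
  if (sum(p1$normal * p2$normal) >= 0)
    warning("portal normals do not point into opposite hemispheres")
  list(portal1 = p1, portal2 = p2)
}

portal_signed_distances <- function(xyz, portal) {
  as.numeric(sweep(xyz, 2, portal$gate_point) %*% portal$normal)
}

#' Classify portal penetration of a pose
#'
#' A portal counts as penetrated when at least `min_atoms` ligand heavy
#' atoms lie beyond its gate plane. Classes: `two_portals` (both breached),
#' `one_portal` (exactly one breached), `none`.
#'
#' @param p A `Pose`.
#' @param portals List with `portal1` and `portal2` definitions.
#' @param min_atoms Protruding-atom threshold (default 1).
#' @return List with `portal_class`, `breach_p1`, `breach_p2`.
#' @export
classify_portal <- function(p, portals, min_atoms = 1L) {
  b1 <- sum(portal_signed_distances(p$xyz, portals$portal1) > 0) >= min_atoms
  b2 <- sum(portal_signed_distances(p$xyz, portals$portal2) > 0) >= min_atoms
  cls <- if (b1 && b2) "two_portals" else if (b1 || b2) "one_portal" else "none"
  list(portal_class = cls, breach_p1 = b1, breach_p2 = b2)
}

#' Classify ring orientation of a pose
#'
#' `epsilon_in` when the epsilon-ring centroid is nearer the portal-2 gate
#' point than the portal-1 gate point (the epsilon ring is buried toward the
#' small, deep portal); `beta_in` otherwise. Exact ties break toward
#' `epsilon_in` and are reported via a message.
#'
#' @param p A `Pose` with ring annotations.
#' @param portals List with `portal1` and `portal2` definitions.
#' @return `"epsilon_in"` or `"beta_in"`.
#' @export
classify_orientation <- function(p, portals) {
  if (is.null(p$rings) || is.null(p$rings$epsilon))
    stop("pose has no ring labels")
  cen <- colMeans(p$xyz[p$rings$epsilon, , drop = FALSE])
  d1 <- vec_norm(cen - portals$portal1$gate_point)
  d2 <- vec_norm(cen - portals$portal2$gate_point)
  if (d1 == d2) message("orientation tie for pose ", p$pose_id,
                        "; classed epsilon_in")
  if (d2 <= d1) "epsilon_in" else "beta_in"
}

#' Classify every pose of a scored ensemble
#'
#' Appends portal and orientation classifications, breach flags and the four
#' overlapping set-membership flags (two-portal, one-portal, epsilon-deep,
#' beta-deep) to a score table.
#'
#' @param ps A `PoseSet`.
#' @param portals List with `portal1` and `portal2` definitions.
#' @param records Score table from [score_ensemble()] (rows in pose order).
#' @param min_atoms Protruding-atom threshold for portal penetration.
#' @return The records with classification columns added.
#' @export
classify_ensemble <- function(ps, portals, records, min_atoms = 1L) {
  stopifnot(nrow(records) == length(ps$poses))
  n <- length(ps$poses)
  pc <- character(n); b1 <- logical(n); b2 <- logical(n); oc <- character(n)
  for (i in seq_len(n)) {
    p <- ps$poses[[i]]
    cp <- classify_portal(p, portals, min_atoms)
    pc[i] <- cp$portal_class; b1[i] <- cp$breach_p1; b2[i] <- cp$breach_p2
    oc[i] <- classify_orientation(p, portals)
  }
  records$portal_class <- pc
  records$breach_p1 <- b1
  records$breach_p2 <- b2
  records$orientation_class <- oc
  records$set_two_portals <- pc == "two_portals"
  records$set_one_portal <- pc == "one_portal" & b1 & !b2
  records$set_epsilon_deep <- oc == "epsilon_in"
  records$set_beta_deep <- oc == "beta_in"
  records
}

#' Serialise portal definitions to a JSON-ready list
#' @param portals List with `portal1` and `portal2`.
#' @export
portals_to_json <- function(portals) {
  lapply(portals, function(p)
    list(label = p$label, gate_point = p$gate_point, normal = p$normal,
         residues = p$residues, aperture = p$aperture))
}
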