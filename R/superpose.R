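# Least-squares rigid-body superposition (Kabsch algorithm via SVD) between
# corresponding point sets, including the end-to-end inverted atom
# correspondence used to dock a conformer in the flipped orientation.

#' Construct a rigid transform
#'
#' @param rotation Proper orthogonal 3 x 3 matrix (det = +1).
#' @param translation Length-3 numeric vector (angstrom).
#' @return A `RigidTransform`.
#' @export
rigid_transform <- function(rotation = diag(3), translation = c(0, 0, 0)) {
  stopifnot(is.matrix(rotation), all(dim(rotation) == c(3, 3)),
            length(translation) == 3)
  if (abs(det(rotation) - 1) > 1e-9)
    stop("rotation must be proper (det = +1)")
  if (max(abs(crossprod(rotation) - diag(3))) > 1e-9)
    stop("rotation must be orthogonal")
  structure(list(rotation = rotation, translation = as.numeric(translation)),
            class = "RigidTransform")
}

#' Apply a rigid transform to coordinates
#'
#' @param tr A `RigidTransform`.
#' @param xyz n x 3 coordinate matrix.
#' @return Transformed n x 3 matrix.
#' @export
apply_transform <- function(tr, xyz) {
  stopifnot(inherits(tr, "RigidTransform"))
  sweep(xyz %*% t(tr$rotation), 2, tr$translation, "+")
}

#' Serialise a rigid transform to a JSON-ready record
#' @param tr A `RigidTransform`.
#' @return List with `rotation` (9 floats, row-major) and `translation`.
#' @export
transform_to_json <- function(tr) {
  list(rotation = as.numeric(t(tr$rotation)), translation = tr$translation)
}

#' Atom correspondence between a moving and a target point set
#'
#' @param moving Integer indices into the moving set.
#' @param target Integer indices into the target set (same length).
#' @param label `"direct"` or `"inverted"`.
#' @return A `Correspondence`.
#' @export
correspondence <- function(moving, target, label = c("direct", "inverted")) {
  label <- match.arg(label)
  stopifnot(length(moving) == length(target))
  if (anyDuplicated(moving) || anyDuplicated(target))
    stop("correspondence indices must be unique within each column")
  if (length(moving) < 3)
    stop("correspondence needs at least 3 pairs")
  structure(list(pairs = cbind(moving = as.integer(moving),
                               target = as.integer(target)),
                 label = label),
            class = "Correspondence")
}

#' Identity correspondence over n atoms
#' @param n Number of atoms.
#' @export
direct_correspondence <- function(n) {
  correspondence(seq_len(n), seq_len(n), "direct")
}

#' End-to-end inverted correspondence of a ligand conformer
#'
#' Pairs each atom with its inversion partner (polyene chain end-for-end,
#' ring skeletons exchanged, hydroxyl O to hydroxyl O), so that a
#' least-squares fit places the conformer in the flipped orientation.
#'
#' @param c A `LigandConformer` with an inversion map.
#' @return A `Correspondence` with label `"inverted"`.
#' @export
inverted_correspondence <- function(c) {
  if (is.null(c$inversion)) stop("conformer has no inversion map")
  correspondence(seq_along(c$inversion), c$inversion, "inverted")
}

## rank check: error out on collinear/coincident point sets
check_nondegenerate <- function(p) {
  sv <- svd(scale(p, scale = FALSE))$d
  if (sv[2] < 1e-8 * max(sv[1], 1))
    stop("degenerate (collinear or coincident) point set")
  invisible(TRUE)
}

#' Least-squares rigid superposition (Kabsch)
#'
#' Finds the proper rotation and translation minimising the RMSD between
#' corresponding points; reflections are excluded by the standard SVD sign
#' correction (the axis of the smallest singular value is flipped when
#' det < 0).
#'
#' @param moving n x 3 coordinates to be moved.
#' @param target m x 3 coordinates to fit onto.
#' @param corr A `Correspondence`; default pairs atoms identically.
#' @return List with `transform` (a `RigidTransform`) and `rmsd` over the
#'   corresponding pairs after transformation.
#' @export
kabsch_fit <- function(moving, target, corr = NULL) {
  moving <- as.matrix(moving); target <- as.matrix(target)
  corr <- corr %||% direct_correspondence(nrow(moving))
  mi <- corr$pairs[, "moving"]; ti <- corr$pairs[, "target"]
  P <- moving[mi, , drop = FALSE]
  Q <- target[ti, , drop = FALSE]
  check_nondegenerate(P)
  check_nondegenerate(Q)
  cp <- colMeans(P); cq <- colMeans(Q)
  Pc <- sweep(P, 2, cp); Qc <- sweep(Q, 2, cq)
  H <- crossprod(Pc, Qc)
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  tvec <- cq - as.numeric(R %*% cp)
  tr <- rigid_transform(R, tvec)
  moved <- apply_transform(tr, P)
  rmsd <- sqrt(mean(rowSums((moved - Q)^2)))
  list(transform = tr, rmsd = rmsd)
}

#' Optimal-fit C-alpha RMSD between two structures
#'
#' Pairs C-alpha atoms by shared (chain, residue number, insertion code),
#' optionally restricted to a residue selection, superposes them and reports
#' the fitted RMSD and pair count. Altloc groups are collapsed to their
#' highest-occupancy conformer first.
#'
#' @param a,b `ProteinStructure` objects.
#' @param resseq Optional residue-number vector restricting the pairing.
#' @return List with `rmsd` (angstrom) and `n_atoms` (number of pairs).
#' @export
ca_rmsd <- function(a, b, resseq = NULL) {
  ca_of <- function(s) {
    at <- collapse_altlocs(s)$atoms
    at <- at[at$name == "CA" & at$element == "C", , drop = FALSE]
    if (!is.null(resseq)) at <- at[at$resseq %in% resseq, , drop = FALSE]
    at$key <- paste(at$chain, at$resseq, at$insert, sep = "|")
    at[!duplicated(at$key), , drop = FALSE]
  }
  ca_a <- ca_of(a); ca_b <- ca_of(b)
  shared <- intersect(ca_a$key, ca_b$key)
  if (length(shared) == 0) stop("no shared C-alpha pairs between structures")
  if (length(shared) < 3) stop("fewer than 3 shared C-alpha pairs")
  ia <- match(shared, ca_a$key); ib <- match(shared, ca_b$key)
  fit <- kabsch_fit(as.matrix(ca_a[ia, c("x", "y", "z")]),
                    as.matrix(ca_b[ib, c("x", "y", "z")]))
  list(rmsd = fit$rmsd, n_atoms = length(shared))
}
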