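# Pose scoring: steric-clash counts (heavy-atom contacts closer than a
# cutoff, strict inequality) and potential-hydrogen-bond counts (ligand
# hydroxyl O within a closed distance window of a protein donor/acceptor).
# Two code paths are kept: an exhaustive all-pairs enumeration (the oracle)
# and a neighbour-grid accelerated path; they must agree exactly.

#' Build a neighbour-grid index over protein atoms
#'
#' Cell-list spatial hash with cell edge equal to the largest distance
#' cutoff in play, so that all partners of a query point lie in its 27
#' surrounding cells.
#'
#' @param xyz n x 3 protein coordinates.
#' @param cell Cell edge length (angstrom); use the largest cutoff needed.
#' @return A `ScoringIndex`.
#' @export
scoring_index <- function(xyz, cell = 4.2) {
  stopifnot(cell > 0)
  xyz <- as.matrix(xyz)
  ix <- floor(xyz[, 1] / cell)
  iy <- floor(xyz[, 2] / cell)
  iz <- floor(xyz[, 3] / cell)
  key <- paste(ix, iy, iz, sep = ",")
  buckets <- split(seq_len(nrow(xyz)), key)
  structure(list(cell = cell, buckets = buckets, xyz = xyz),
            class = "ScoringIndex")
}

## candidate protein atoms within the 27-cell neighbourhood of point p
index_candidates <- function(idx, p) {
  ci <- floor(p / idx$cell)
  keys <- as.vector(outer(
    as.vector(outer(ci[1] + (-1:1), ci[2] + (-1:1),
                    function(a, b) paste(a, b, sep = ","))),
    ci[3] + (-1:1), function(ab, c) paste(ab, c, sep = ",")))
  unlist(idx$buckets[keys], use.names = FALSE)
}

protein_heavy_xyz <- function(protein, include_solvent = FALSE) {
  atom_xyz(docking_atoms(protein, include_solvent = include_solvent))
}

count_within <- function(lig_xyz, prot_xyz, cutoff, idx = NULL,
                         per = c("pair", "atom")) {
  per <- match.arg(per)
  if (nrow(prot_xyz) == 0) return(0L)
  if (is.null(idx)) {
    d <- cross_dist(lig_xyz, prot_xyz)
    hits <- d < cutoff
  } else {
    hits <- matrix(FALSE, nrow(lig_xyz), 1)
    n_per_atom <- integer(nrow(lig_xyz))
    for (i in seq_len(nrow(lig_xyz))) {
      cand <- index_candidates(idx, lig_xyz[i, ])
      if (length(cand) == 0) next
      d <- dist_to_rows(lig_xyz[i, ], idx$xyz[cand, , drop = FALSE])
      n_per_atom[i] <- sum(d < cutoff)
    }
    return(if (per == "pair") sum(n_per_atom) else sum(n_per_atom > 0L))
  }
  if (per == "pair") sum(hits) else sum(rowSums(hits) > 0L)
}

#' Steric clash count for a pose
#'
#' Counts ligand/protein heavy-atom pairs closer than the threshold
#' (strictly less than; a contact at exactly the threshold is not a clash).
#' Waters and crystallisation additives are excluded from the protein set
#' by default.
#'
#' @param p A `Pose` (or any object with an `xyz` matrix).
#' @param protein A `ProteinStructure`.
#' @param threshold Clash cutoff in angstrom (default 3.0).
#' @param method `"grid"` (cell-list accelerated) or `"exhaustive"`
#'   (all-pairs oracle). Both give identical counts.
#' @param per Count `"pair"`s (default) or ligand `"atom"`s with at least
#'   one clash.
#' @param include_solvent Keep waters/additives in the protein set.
#' @param index Optional prebuilt [scoring_index()] over the same atom set
#'   (its cell must be >= threshold).
#' @return Integer clash count.
#' @export
clash_score <- function(p, protein, threshold = 3.0,
                        method = c("grid", "exhaustive"),
                        per = c("pair", "atom"),
                        include_solvent = FALSE, index = NULL) {
  method <- match.arg(method); per <- match.arg(per)
  lig <- p$xyz
  if (method == "exhaustive") {
    prot <- protein_heavy_xyz(protein, include_solvent)
    return(as.integer(count_within(lig, prot, threshold, NULL, per)))
  }
  if (is.null(index)) {
    prot <- protein_heavy_xyz(protein, include_solvent)
    index <- scoring_index(prot, cell = max(threshold, 0.1))
  } else if (index$cell < threshold) {
    stop("scoring index cell (", index$cell, ") smaller than threshold")
  }
  as.integer(count_within(lig, index$xyz, threshold, index, per))
}

polar_protein_atoms <- function(protein, include_solvent = FALSE) {
  s <- docking_atoms(protein, include_solvent = include_solvent)
  a <- s$atoms
  if (anyNA(a$polar_role))
    stop("protein polar roles are not assigned; run assign_polar_roles() first")
  a[a$polar_role %in% c("donor", "acceptor", "both"), , drop = FALSE]
}

#' Potential-hydrogen-bond count for a pose
#'
#' Counts (ligand hydroxyl oxygen, protein donor-or-acceptor atom) pairs
#' whose distance lies in the closed window. Both hydroxyls are eligible and
#' every in-window partner of each hydroxyl is counted. The criterion is
#' purely distance-based (no angle term), on heavy atoms.
#'
#' @inheritParams clash_score
#' @param window Closed distance window in angstrom (default `c(2.0, 4.2)`).
#' @param index Optional [scoring_index()] over the polar atom subset (cell
#'   >= `window[2]`).
#' @return List with `count` and `partners` (data frame: hydroxyl atom name,
#'   protein atom descriptor, distance).
#' @export
hbond_score <- function(p, protein, window = c(2.0, 4.2),
                        method = c("grid", "exhaustive"),
                        include_solvent = FALSE, index = NULL) {
  method <- match.arg(method)
  stopifnot(length(window) == 2, window[1] <= window[2])
  if (is.null(p$hydroxyl)) stop("pose has no annotated hydroxyl oxygens")
  hx <- p$xyz[p$hydroxyl, , drop = FALSE]
  if (is.null(index)) {
    polar <- polar_protein_atoms(protein, include_solvent)
    pxyz <- as.matrix(polar[, c("x", "y", "z")])
    idx <- if (method == "grid" && nrow(pxyz) > 0)
      scoring_index(pxyz, cell = max(window[2], 0.1)) else NULL
  } else {
    if (index$cell < window[2])
      stop("scoring index cell smaller than the window upper bound")
    polar <- attr(index, "polar_atoms")
    pxyz <- index$xyz
    idx <- if (method == "grid") index else NULL
  }
  partners <- list()
  count <- 0L
  for (h in seq_len(nrow(hx))) {
    cand <- if (is.null(idx)) seq_len(nrow(pxyz))
            else index_candidates(idx, hx[h, ])
    if (length(cand) == 0) next
    d <- dist_to_rows(hx[h, ], pxyz[cand, , drop = FALSE])
    inw <- d >= window[1] & d <= window[2]
    if (!any(inw)) next
    count <- count + sum(inw)
    hit <- cand[inw]
    desc <- if (!is.null(polar))
      paste0(polar$resname[hit], polar$resseq[hit], ":", polar$name[hit])
    else as.character(hit)
    partners[[length(partners) + 1L]] <- data.frame(
      hydroxyl = p$atoms$name[p$hydroxyl[h]], protein_atom = desc,
      distance = d[inw], stringsAsFactors = FALSE)
  }
  partners <- if (length(partners) > 0) do.call(rbind, partners)
  else data.frame(hydroxyl = character(), protein_atom = character(),
                  distance = numeric())
  list(count = as.integer(count), partners = partners)
}

#' Build the clash and H-bond indices for repeated scoring
#' @keywords internal
build_scoring_indices <- function(protein, clash_threshold, hbond_window,
                                  include_solvent = FALSE) {
  prot <- protein_heavy_xyz(protein, include_solvent)
  cell <- max(clash_threshold, hbond_window[2], 0.1)
  clash_idx <- scoring_index(prot, cell = cell)
  polar <- polar_protein_atoms(protein, include_solvent)
  hb_idx <- scoring_index(as.matrix(polar[, c("x", "y", "z")]), cell = cell)
  attr(hb_idx, "polar_atoms") <- polar
  list(clash = clash_idx, hbond = hb_idx)
}

#' Score every pose of an ensemble
#'
#' @param ps A `PoseSet`.
#' @param protein A `ProteinStructure` with polar roles assigned.
#' @param clash_threshold Clash cutoff (angstrom, default 3.0).
#' @param hbond_window H-bond distance window (default `c(2.0, 4.2)`).
#' @param method `"grid"` or `"exhaustive"`.
#' @param per Clash counting mode, `"pair"` or `"atom"`.
#' @param include_solvent Keep waters/additives.
#' @param model_label Protein conformer-model label recorded per pose.
#' @return Data frame with one row per pose: `pose_id`, `template`,
#'   `conformer`, `orientation`, `clashes`, `hbonds`, `model`.
#' @export
score_ensemble <- function(ps, protein, clash_threshold = 3.0,
                           hbond_window = c(2.0, 4.2),
                           method = c("grid", "exhaustive"),
                           per = c("pair", "atom"),
                           include_solvent = FALSE, model_label = "base") {
  method <- match.arg(method); per <- match.arg(per)
  idx <- if (method == "grid")
    build_scoring_indices(protein, clash_threshold, hbond_window,
                          include_solvent)
  else list(clash = NULL, hbond = NULL)
  n <- length(ps$poses)
  clashes <- integer(n); hbonds <- integer(n)
  for (i in seq_len(n)) {
    p <- ps$poses[[i]]
    clashes[i] <- clash_score(p, protein, clash_threshold, method, per,
                              include_solvent, index = idx$clash)
    hbonds[i] <- hbond_score(p, protein, hbond_window, method,
                             include_solvent, index = idx$hbond)$count
  }
  data.frame(
    pose_id = vapply(ps$poses, `[[`, "", "pose_id"),
    template = vapply(ps$poses, `[[`, 0L, "template"),
    conformer = vapply(ps$poses, `[[`, 0L, "conformer"),
    orientation = vapply(ps$poses, `[[`, "", "orientation"),
    clashes = clashes, hbonds = hbonds, model = model_label,
    stringsAsFactors = FALSE)
}

#' Pick the winning pose record
#'
#' Minimal clash count; ties broken by more hydrogen bonds, then by
#' lexicographic pose id.
#'
#' @param records Score data frame from [score_ensemble()].
#' @param eligible Optional logical vector (or filtering function) applied
#'   to the records first.
#' @return The single winning record (one-row data frame).
#' @export
pick_winner <- function(records, eligible = NULL) {
  if (!is.null(eligible)) {
    keep <- if (is.function(eligible)) eligible(records) else eligible
    records <- records[keep, , drop = FALSE]
  }
  if (nrow(records) == 0) stop("no eligible records to pick a winner from")
  ord <- order(records$clashes, -records$hbonds, records$pose_id)
  records[ord[1], , drop = FALSE]
}
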