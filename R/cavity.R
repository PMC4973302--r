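# Grid/probe cavity detection and geometric characterisation. Voxels within
# vdW + probe of any protein atom are protein; exterior solvent is labelled
# bulk by flood fill from the grid boundary; remaining interior voxels are
# cavity. Volume, through-cavity tunnel length and enclosed-solvent counts
# are derived from the labelled grid.

VDW_RADII <- c(H = 1.20, D = 1.20, C = 1.70, N = 1.55, O = 1.52, S = 1.80,
               P = 1.80, SE = 1.90, F = 1.47, CL = 1.75, BR = 1.85,
               I = 1.98, NA_ = 2.27, K = 2.75, MG = 1.73, CA = 2.31,
               ZN = 1.39, FE = 1.40, MN = 1.40, CU = 1.40)
DEFAULT_VDW <- 1.70

vdw_radius <- function(element) {
  r <- VDW_RADII[element]
  r[is.na(r)] <- DEFAULT_VDW
  unname(r)
}

## shift a 3d array by one voxel along axis (1..3), direction (+1/-1),
## padding with `fill`
shift3d <- function(arr, axis, dir, fill) {
  d <- dim(arr)
  out <- array(fill, dim = d)
  src <- dst <- list(seq_len(d[1]), seq_len(d[2]), seq_len(d[3]))
  if (dir > 0) { dst[[axis]] <- 2:d[axis]; src[[axis]] <- 1:(d[axis] - 1) }
  else { dst[[axis]] <- 1:(d[axis] - 1); src[[axis]] <- 2:d[axis] }
  out[dst[[1]], dst[[2]], dst[[3]]] <- arr[src[[1]], src[[2]], src[[3]]]
  out
}

dilate6 <- function(mask) {
  out <- mask
  for (axis in 1:3) for (dir in c(-1, 1))
    out <- out | shift3d(mask, axis, dir, FALSE)
  out
}

## grow a seed region inside `allowed` until stable (6-connectivity)
flood_region <- function(seed, allowed) {
  region <- seed & allowed
  repeat {
    grown <- dilate6(region) & allowed
    if (sum(grown) == sum(region)) return(region)
    region <- grown
  }
}

#' Detect interior cavities on a probe-inflated voxel grid
#'
#' @param protein A `ProteinStructure` (waters/additives excluded by
#'   default via [docking_atoms()]).
#' @param spacing Voxel edge in angstrom, in (0.2, 1.5].
#' @param probe Probe radius in angstrom (default 1.4, water-sized).
#' @param include_solvent Keep waters/additives in the occupying atom set.
#' @param margin Padding around the atom bounding box (angstrom).
#' @return A `CavityGrid`: label array (`"bulk"`, `"protein"`, `"cavity"`,
#'   `"cavity_minor"`), voxel geometry, volume of the largest cavity
#'   component and the component count. An absent cavity gives volume 0.
#' @export
detect_cavity <- function(protein, spacing = 0.5, probe = 1.4,
                          include_solvent = FALSE, margin = NULL) {
  stopifnot(spacing > 0.2, spacing <= 1.5)
  s <- docking_atoms(protein, include_solvent = include_solvent)
  xyz <- atom_xyz(s)
  if (nrow(xyz) == 0) stop("protein has no atoms")
  radii <- vdw_radius(s$atoms$element) + probe
  margin <- margin %||% (max(radii) + 2 * spacing)
  lo <- apply(xyz, 2, min) - margin
  hi <- apply(xyz, 2, max) + margin
  dims <- pmax(3L, as.integer(ceiling((hi - lo) / spacing)))
  prot <- array(FALSE, dim = dims)
  # stamp each atom's inflated sphere onto the grid
  for (i in seq_len(nrow(xyz))) {
    r <- radii[i]
    ctr <- (xyz[i, ] - lo) / spacing + 0.5  # voxel-index space (centres at k)
    i0 <- pmax(1L, as.integer(floor(ctr - r / spacing)))
    i1 <- pmin(dims, as.integer(ceiling(ctr + r / spacing)))
    if (any(i0 > i1)) next
    gx <- i0[1]:i1[1]; gy <- i0[2]:i1[2]; gz <- i0[3]:i1[3]
    dx2 <- ((gx - ctr[1]) * spacing)^2
    dy2 <- ((gy - ctr[2]) * spacing)^2
    dz2 <- ((gz - ctr[3]) * spacing)^2
    within <- outer(outer(dx2, dy2, "+"), dz2, "+") <= r^2
    blk <- prot[gx, gy, gz]
    prot[gx, gy, gz] <- blk | within
  }
  # flood fill bulk solvent from the grid boundary
  boundary <- array(FALSE, dim = dims)
  boundary[c(1, dims[1]), , ] <- TRUE
  boundary[, c(1, dims[2]), ] <- TRUE
  boundary[, , c(1, dims[3])] <- TRUE
  bulk <- flood_region(boundary & !prot, !prot)
  cav <- !prot & !bulk
  # connected components of the cavity; keep the largest as the cavity
  comp <- array(0L, dim = dims)
  ncomp <- 0L
  sizes <- integer(0)
  remaining <- cav
  while (any(remaining)) {
    seed <- array(FALSE, dim = dims)
    seed[which(remaining)[1]] <- TRUE
    region <- flood_region(seed, remaining)
    ncomp <- ncomp + 1L
    comp[region] <- ncomp
    sizes[ncomp] <- sum(region)
    remaining <- remaining & !region
  }
  main <- if (ncomp > 0) which.max(sizes) else 0L
  label <- array("bulk", dim = dims)
  label[prot] <- "protein"
  if (ncomp > 0) {
    label[cav] <- "cavity_minor"
    label[comp == main] <- "cavity"
  }
  structure(list(
    label = label, spacing = spacing, probe = probe, origin = lo,
    dims = dims, n_components = ncomp,
    volume = if (ncomp > 0) sizes[main] * spacing^3 else 0,
    component_sizes = sizes),
    class = "CavityGrid")
}

#' @export
print.CavityGrid <- function(x, ...) {
  cat("CavityGrid: ", paste(x$dims, collapse = " x "), " voxels @ ",
      x$spacing, " A; largest cavity ", sprintf("%.0f", x$volume),
      " A^3 (", x$n_components, " component(s))\n", sep = "")
  invisible(x)
}

## voxel centre coordinates of a logical mask
voxel_centers <- function(g, mask) {
  idx <- which(mask, arr.ind = TRUE)
  sweep((idx - 0.5) * g$spacing, 2, g$origin, "+")
}

## voxel (array) index of points; NA rows when off-grid
voxel_index_of <- function(g, xyz) {
  idx <- floor(sweep(as.matrix(xyz), 2, g$origin) / g$spacing) + 1
  bad <- idx[, 1] < 1 | idx[, 1] > g$dims[1] |
         idx[, 2] < 1 | idx[, 2] > g$dims[2] |
         idx[, 3] < 1 | idx[, 3] > g$dims[3]
  idx[bad, ] <- NA
  idx
}

#' Through-cavity tunnel length
#'
#' Geodesic length of the shortest path through cavity voxels between the
#' two portal-adjacent voxel patches. With portal definitions supplied, each
#' patch is the set of cavity voxels nearest that portal's gate point and
#' the gate-to-patch gaps are included in the length; without portals the
#' patches are taken as cavity voxels adjacent to bulk (open tunnels).
#'
#' @param g A `CavityGrid`.
#' @param portals Optional list with `portal1` and `portal2` definitions.
#' @return Length in angstrom.
#' @export
tunnel_length <- function(g, portals = NULL) {
  cav <- g$label == "cavity"
  if (!any(cav)) stop("empty cavity")
  # crop to the cavity bounding box (plus one voxel) for speed
  idx <- which(cav, arr.ind = TRUE)
  lo <- pmax(apply(idx, 2, min) - 1L, 1L)
  hi <- pmin(apply(idx, 2, max) + 1L, g$dims)
  sub <- cav[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE]
  sub_origin <- g$origin + (lo - 1) * g$spacing
  centers_of <- function(mask) {
    ii <- which(mask, arr.ind = TRUE)
    sweep((ii - 0.5) * g$spacing, 2, sub_origin, "+")
  }
  if (is.null(portals)) {
    bulk <- (g$label == "bulk")[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3],
                                drop = FALSE]
    mouth <- sub & dilate6(bulk)
    if (!any(mouth)) stop("fewer than two portal patches (sealed cavity); supply portal definitions")
    # split mouth voxels into connected patches
    patches <- list()
    remaining <- mouth
    while (any(remaining)) {
      seed <- array(FALSE, dim = dim(sub)); seed[which(remaining)[1]] <- TRUE
      region <- flood_region(seed, remaining)
      patches[[length(patches) + 1L]] <- region
      remaining <- remaining & !region
    }
    if (length(patches) < 2) stop("fewer than two portal patches")
    sizes <- vapply(patches, sum, 0L)
    ord <- order(-sizes)
    seed_mask <- patches[[ord[1]]]; target_mask <- patches[[ord[2]]]
    seed_init <- 0; gate2 <- NULL
  } else {
    cxyz <- centers_of(sub)
    d1 <- dist_to_rows(portals$portal1$gate_point, cxyz)
    d2 <- dist_to_rows(portals$portal2$gate_point, cxyz)
    pick <- function(d) {
      m <- min(d)
      sel <- array(FALSE, dim = dim(sub))
      sel[which(sub)[d <= m + g$spacing]] <- TRUE
      sel
    }
    seed_mask <- pick(d1); target_mask <- pick(d2)
    seed_init <- min(d1); gate2 <- portals$portal2$gate_point
  }
  # chamfer distance propagation (26-neighbourhood) through cavity voxels
  w1 <- g$spacing; w2 <- sqrt(2) * g$spacing; w3 <- sqrt(3) * g$spacing
  field <- array(Inf, dim = dim(sub))
  field[seed_mask] <- seed_init
  shifts <- expand.grid(dx = -1:1, dy = -1:1, dz = -1:1)
  shifts <- shifts[rowSums(abs(shifts)) > 0, ]
  wts <- c(w1, w2, w3)[rowSums(abs(shifts))]
  shift_once <- function(arr, s) {
    out <- arr
    if (s[1] != 0) out <- shift3d(out, 1, s[1], Inf)
    if (s[2] != 0) out <- shift3d(out, 2, s[2], Inf)
    if (s[3] != 0) out <- shift3d(out, 3, s[3], Inf)
    out
  }
  repeat {
    prev <- field
    for (k in seq_len(nrow(shifts))) {
      cand <- shift_once(field, as.numeric(shifts[k, ])) + wts[k]
      upd <- cand < field & sub
      field[upd] <- cand[upd]
    }
    if (identical(prev, field)) break
  }
  tvals <- field[target_mask]
  if (all(!is.finite(tvals)))
    stop("portal patches are not connected through the cavity")
  if (is.null(gate2)) return(min(tvals))
  txyz <- centers_of(target_mask)
  min(tvals + dist_to_rows(gate2, txyz))
}

#' Count solvent molecules enclosed in the cavity
#'
#' A solvent molecule counts when its oxygen (or, failing that, its
#' centroid-nearest atom) falls in a voxel of the largest cavity component.
#'
#' @param g A `CavityGrid`.
#' @param s A `ProteinStructure` with solvent retained.
#' @param solvent_resnames Residue names treated as solvent.
#' @return Integer count.
#' @export
count_enclosed_solvent <- function(g, s,
                                   solvent_resnames = c(SOLVENT_RESNAMES,
                                                        ADDITIVE_RESNAMES)) {
  a <- s$atoms
  sol <- a[a$resname %in% solvent_resnames, , drop = FALSE]
  if (nrow(sol) == 0) return(0L)
  key <- paste(sol$chain, sol$resseq, sol$resname, sep = "|")
  count <- 0L
  for (k in unique(key)) {
    mol <- sol[key == k, , drop = FALSE]
    ox <- which(mol$element == "O")
    central <- if (length(ox) > 0) ox[1] else {
      cen <- colMeans(as.matrix(mol[, c("x", "y", "z")]))
      which.min(dist_to_rows(cen, as.matrix(mol[, c("x", "y", "z")])))
    }
    vi <- voxel_index_of(g, mol[central, c("x", "y", "z")])
    if (anyNA(vi)) next
    if (g$label[vi[1, 1], vi[1, 2], vi[1, 3]] == "cavity")
      count <- count + 1L
  }
  count
}
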