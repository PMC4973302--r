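# Fully synthetic test systems: parameterised tunnel-shaped protein walls
# with two unequal portals and a deep narrow pocket (the planted orientation
# ground truth), plus rigid curved two-ring diol ligand conformer libraries
# mirroring the geometry of a xanthophyll (terminal hydroxyl span ~30.5 A,
# one larger and one smaller terminal ring).
#
# Wall pseudo-atoms are carbon; their centres sit at the target cavity
# radius plus vdW(C) + probe, so the probe-inflated molecular surface lands
# on the nominal cavity wall and a < 3 A clash corresponds to a ligand atom
# within ~0.1 A of that wall.

SYNTH_PROBE <- 1.4
SYNTH_RINF <- 1.70 + SYNTH_PROBE  # carbon vdW + water probe

#' Specification of a synthetic tunnel protein
#'
#' The tunnel runs along x from -length/2 (portal 2, the small deep opening)
#' to +length/2 (portal 1, the large opening). With `pocket = TRUE` the deep
#' quarter of the tunnel narrows to `radius_portal2` — a pocket that admits
#' only the small terminal ring of the companion ligand; the shallow half
#' keeps `radius_portal1`.
#'
#' @param length Tunnel length, angstrom (default 20).
#' @param radius_portal1 Cavity radius of the shallow half (default 4.0).
#' @param radius_portal2 Pocket cavity radius at the deep end (default 1.8).
#' @param pocket Plant the small-ring-only pocket (default TRUE). With
#'   FALSE the cavity is a uniform cylinder of radius `radius_portal1`.
#' @param portal1_hole,portal2_hole Open aperture radii of the two end
#'   portals (must be smaller than vdW + probe so the probe-inflated
#'   surface seals them).
#' @param wall_spacing Spacing of wall pseudo-atoms, angstrom.
#' @param polar_sites Place hydrogen-bonding sites on the tunnel axis
#'   beyond the two portals.
#' @param polar_site_x Axial positions of the polar sites. They sit on the
#'   axis so that ligand hydroxyl tips (which lie on the molecular axis)
#'   reach them through the portal apertures while terminal rings stay
#'   well outside clash range in either orientation; the defaults are
#'   co-designed with the default ligand span (30.5) and template depth
#'   grid (5.75-8).
#' @param seed Stored for provenance; generation is deterministic.
#' @return A `TunnelSpec`.
#' @export
tunnel_spec <- function(length = 20, radius_portal1 = 4.0,
                        radius_portal2 = 1.8, pocket = TRUE,
                        portal1_hole = 2.5, portal2_hole = 1.2,
                        wall_spacing = 1.2, polar_sites = TRUE,
                        polar_site_x = c(-13.5, -12.7, 26.45, 27.25),
                        seed = 1L) {
  if (radius_portal2 <= 0 || radius_portal1 < radius_portal2)
    stop("portal radii must satisfy r1 >= r2 > 0")
  if (portal1_hole >= SYNTH_RINF - 0.2 || portal2_hole >= SYNTH_RINF - 0.2)
    stop("portal holes too wide to seal under the probe-inflated surface")
  if (length <= 2 * wall_spacing) stop("tunnel too short")
  structure(list(length = length, radius_portal1 = radius_portal1,
                 radius_portal2 = radius_portal2, pocket = pocket,
                 portal1_hole = portal1_hole, portal2_hole = portal2_hole,
                 wall_spacing = wall_spacing, polar_sites = polar_sites,
                 polar_site_x = polar_site_x, seed = seed),
            class = "TunnelSpec")
}

#' Symmetric (null) tunnel spec: equal portals, no pocket
#' @param ... Overrides passed to [tunnel_spec()].
#' @export
symmetric_tunnel_spec <- function(...) {
  args <- list(...)
  defaults <- list(pocket = FALSE, radius_portal2 = 4.0,
                   portal2_hole = 2.5)
  for (nm in names(defaults))
    if (is.null(args[[nm]])) args[[nm]] <- defaults[[nm]]
  do.call(tunnel_spec, args)
}

## nominal cavity radius profile r(x)
tunnel_radius_profile <- function(spec, x) {
  L <- spec$length; r1 <- spec$radius_portal1; r2 <- spec$radius_portal2
  if (!spec$pocket) return(rep(r1, length(x)))
  r <- rep(r1, length(x))
  deep <- x <= -L / 4
  trans <- x > -L / 4 & x < 0
  r[deep] <- r2
  r[trans] <- r2 + (x[trans] + L / 4) / (L / 4) * (r1 - r2)
  r
}

#' Nominal (analytic) cavity volume of a tunnel spec
#'
#' Volume of revolution of the nominal radius profile (pi * integral of
#' r(x)^2 dx) minus the analytic end-cap erosion: over the annulus between
#' each portal hole and the local cavity radius, the probe-inflated cap
#' surface cuts the cavity short by rinf - sqrt(rinf^2 - hole^2), where
#' rinf is the carbon vdW radius plus the probe radius.
#'
#' @param spec A `TunnelSpec`.
#' @return Volume in cubic angstrom.
#' @export
tunnel_nominal_volume <- function(spec) {
  L <- spec$length; r1 <- spec$radius_portal1; r2 <- spec$radius_portal2
  profile <- if (!spec$pocket) pi * r1^2 * L
  else pi * (r2^2 * (L / 4) +
               (L / 4) * (r2^2 + r2 * r1 + r1^2) / 3 +
               r1^2 * (L / 2))
  r_end <- tunnel_radius_profile(spec, c(L / 2, -L / 2))
  holes <- c(spec$portal1_hole, spec$portal2_hole)
  erosion <- sum((SYNTH_RINF - sqrt(SYNTH_RINF^2 - holes^2)) *
                   pi * pmax(r_end^2 - holes^2, 0))
  profile - erosion
}

ring_of_atoms <- function(x, radius, n, phase = 0) {
  ang <- phase + 2 * pi * (seq_len(n) - 1) / n
  cbind(x = rep(x, n), y = radius * cos(ang), z = radius * sin(ang))
}

#' Generate a synthetic tunnel protein
#'
#' Builds the wall pseudo-atom lattice (tube plus sealed end caps with the
#' two portal holes), places polar hydrogen-bonding sites outside both
#' portals, and emits the portal gate definitions and ground-truth metadata.
#'
#' @param spec A `TunnelSpec`.
#' @return List with `structure` (a `ProteinStructure`), `portals`
#'   (portal 1 and 2 definitions) and `metadata` (ground truth: which
#'   orientation the pocket favours, axis, nominal volume).
#' @export
make_tunnel_protein <- function(spec) {
  stopifnot(inherits(spec, "TunnelSpec"))
  L <- spec$length; ws <- spec$wall_spacing
  pts <- list(); roles <- character(0); resn <- character(0)
  add <- function(xyz, role, resname) {
    pts[[length(pts) + 1L]] <<- xyz
    roles <<- c(roles, rep(role, nrow(xyz)))
    resn <<- c(resn, rep(resname, nrow(xyz)))
  }
  # tube wall
  stations <- seq(-L / 2, L / 2, by = ws)
  for (si in seq_along(stations)) {
    x <- stations[si]
    R <- tunnel_radius_profile(spec, x) + SYNTH_RINF
    n <- max(8L, ceiling(2 * pi * R / ws))
    add(ring_of_atoms(x, R, n, phase = (si %% 2) * pi / n), "none", "TUN")
  }
  # sealed end caps with portal holes
  for (side in c(1, -1)) {
    hole <- if (side > 0) spec$portal1_hole else spec$portal2_hole
    r_end <- tunnel_radius_profile(spec, side * L / 2) + SYNTH_RINF
    xc <- side * (L / 2 + sqrt(SYNTH_RINF^2 - hole^2))
    radii <- unique(c(seq(hole, r_end, by = ws), r_end))
    for (ri in seq_along(radii)) {
      n <- max(6L, ceiling(2 * pi * radii[ri] / ws))
      add(ring_of_atoms(xc, radii[ri], n, phase = (ri %% 2) * pi / n),
          "none", "TUN")
    }
  }
  # on-axis polar sites beyond the two portals; ligand hydroxyl tips reach
  # them through the apertures, terminal rings never do
  if (spec$polar_sites && length(spec$polar_site_x) > 0) {
    add(cbind(x = spec$polar_site_x, y = 0, z = 0), "both", "POL")
  }
  xyz <- do.call(rbind, pts)
  n <- nrow(xyz)
  atoms <- data.frame(
    type = "HETATM", serial = seq_len(n),
    name = ifelse(roles == "both", "O", "C"), altloc = "",
    resname = resn, chain = "A", resseq = seq_len(n), insert = "",
    x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
    occupancy = 1.0, bfactor = 0.0,
    element = ifelse(roles == "both", "O", "C"),
    polar_role = roles, stringsAsFactors = FALSE)
  s <- new_protein_structure(atoms, id = "synthetic_tunnel")
  portals <- list(
    portal1 = portal_definition("portal1", c(L / 2, 0, 0), c(1, 0, 0),
                                aperture = rep(2 * spec$portal1_hole, 2)),
    portal2 = portal_definition("portal2", c(-L / 2, 0, 0), c(-1, 0, 0),
                                aperture = rep(2 * spec$portal2_hole, 2)))
  metadata <- list(
    axis = c(1, 0, 0), center = c(0, 0, 0), length = L,
    favored_orientation = if (spec$pocket) "epsilon_in" else NA_character_,
    nominal_volume = tunnel_nominal_volume(spec), spec = spec)
  list(structure = s, portals = portals, metadata = metadata)
}

#' Specification of a synthetic rigid two-ring diol ligand
#'
#' A curved polyene-like backbone with a small terminal ring (labelled
#' epsilon) and a large terminal ring (labelled beta), each carrying one
#' hydroxyl oxygen at the molecular tip; the tips are `span` apart.
#'
#' @param span Hydroxyl O-O distance, angstrom (default 30.5).
#' @param bow Backbone bow (parabolic sagitta at mid-chain), angstrom.
#' @param bow_sd Per-conformer standard deviation of the bow.
#' @param small_ring_radius,large_ring_radius Terminal ring radii.
#' @param ring_inset Axial inset of ring centres from the hydroxyl tips.
#' @param n_backbone Number of backbone atoms.
#' @param n_conformers Library size (default 320; large enough that the
#'   default single-template study design yields well-populated top
#'   groups of mutually independent poses).
#' @param jitter Per-atom coordinate noise sd, angstrom (default 0.1).
#' @param seed RNG seed for the library.
#' @return A `LigandSpec`.
#' @export
ligand_spec <- function(span = 30.5, bow = 1.0, bow_sd = 0.1,
                        small_ring_radius = 1.35, large_ring_radius = 2.30,
                        ring_inset = 1.0, n_backbone = 17L,
                        n_conformers = 320L, jitter = 0.1, seed = 1L) {
  if (span <= 4 * ring_inset) stop("span too short for the ring insets")
  if (small_ring_radius >= large_ring_radius)
    stop("small ring must be smaller than the large ring")
  if (jitter >= small_ring_radius / 2)
    stop("jitter so large that ring labels become ambiguous")
  structure(list(span = span, bow = bow, bow_sd = bow_sd,
                 small_ring_radius = small_ring_radius,
                 large_ring_radius = large_ring_radius,
                 ring_inset = ring_inset, n_backbone = as.integer(n_backbone),
                 n_conformers = as.integer(n_conformers), jitter = jitter,
                 seed = seed),
            class = "LigandSpec")
}

synthetic_ligand_atom_names <- function(spec) {
  c("O1", paste0("CS", 1:6),
    sprintf("CB%02d", seq_len(spec$n_backbone)),
    paste0("CL", 1:6), "O2")
}

## register the synthetic species so file round-trips work
register_synthetic_species <- function(spec, residue_name = "SYN") {
  nm <- synthetic_ligand_atom_names(spec)
  nb <- spec$n_backbone
  inv <- c(stats::setNames("O2", "O1"),
           stats::setNames(paste0("CL", 1:6), paste0("CS", 1:6)),
           stats::setNames(sprintf("CB%02d", nb:1),
                           sprintf("CB%02d", seq_len(nb))))
  register_ligand_species(
    residue_name, heavy_atoms = nm, hydroxyl = c("O1", "O2"),
    rings = list(beta = paste0("CL", 1:6), epsilon = paste0("CS", 1:6)),
    inversion = inv)
}

## ideal (noise-free) ligand coordinates for a given bow
base_ligand_xyz <- function(spec, bow = spec$bow) {
  S <- spec$span
  xs_small <- -S / 2 + spec$ring_inset
  xs_large <- S / 2 - spec$ring_inset
  small <- ring_of_atoms(xs_small, spec$small_ring_radius, 6)
  large <- ring_of_atoms(xs_large, spec$large_ring_radius, 6)
  bx <- seq(-S / 2 + 2.2, S / 2 - 2.2, length.out = spec$n_backbone)
  backbone <- cbind(x = bx, y = 0, z = bow * (1 - (2 * bx / S)^2))
  rbind(c(-S / 2, 0, 0), small, backbone, large, c(S / 2, 0, 0))
}

make_synthetic_conformer <- function(spec, xyz, idx) {
  nm <- synthetic_ligand_atom_names(spec)
  nb <- spec$n_backbone
  n <- length(nm)
  atoms <- data.frame(name = nm,
                      element = ifelse(substr(nm, 1, 1) == "O", "O", "C"),
                      x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
                      stringsAsFactors = FALSE)
  inversion <- integer(n)
  inversion[1] <- n; inversion[n] <- 1L
  inversion[2:7] <- (n - 6):(n - 1)          # CS -> CL
  inversion[(n - 6):(n - 1)] <- 2:7          # CL -> CS
  inversion[8:(7 + nb)] <- (7 + nb):8        # backbone end-for-end
  new_ligand_conformer(atoms, hydroxyl = c(1L, n),
                       rings = list(beta = (n - 6):(n - 1), epsilon = 2:7),
                       inversion = inversion,
                       source = list(structure_id = "synthetic", chain = "X",
                                     resseq = idx))
}

#' Generate a synthetic ligand conformer library
#'
#' Conformers share atom count and ordering; each is the ideal ligand with
#' a per-conformer bow drawn around the spec's bow and independent Gaussian
#' coordinate jitter. With zero jitter and zero bow spread all conformers
#' are identical and the hydroxyl span equals the spec's span exactly.
#'
#' @param spec A `LigandSpec`.
#' @return List of `LigandConformer` (length `n_conformers`).
#' @export
make_ligand_library <- function(spec) {
  stopifnot(inherits(spec, "LigandSpec"))
  register_synthetic_species(spec)
  with_seed(spec$seed, {
    lapply(seq_len(spec$n_conformers), function(j) {
      bow_j <- spec$bow + stats::rnorm(1, 0, spec$bow_sd)
      xyz <- base_ligand_xyz(spec, bow_j)
      xyz <- xyz + matrix(stats::rnorm(length(xyz), 0, spec$jitter),
                          ncol = 3)
      make_synthetic_conformer(spec, xyz, j)
    })
  })
}

#' Generate docking templates along the tunnel axis
#'
#' Places the ideal ligand (small/epsilon ring toward portal 2) at evenly
#' spaced depths along the cavity axis and axial roll angles, standing in
#' for manually positioned template molecules. Deterministic.
#'
#' @param metadata Tunnel metadata from [make_tunnel_protein()].
#' @param lig_spec A `LigandSpec` (the template geometry).
#' @param n_depths,n_rolls Grid dimensions (default 1 x 1). The default
#'   study design uses a single template so that every pose in the scored
#'   ensemble carries a distinct conformer per orientation, keeping
#'   top-group members statistically independent for the chi-squared
#'   test; denser grids are available for exploration but make poses of
#'   the same conformer correlated.
#' @param depth_range Depth offsets toward portal 1, angstrom (default
#'   `c(8, 8)`; co-designed with the default on-axis polar sites of
#'   [tunnel_spec()] so the hydroxyl tips reach a site).
#' @return List of placed `LigandConformer` templates (length
#'   `n_depths * n_rolls`).
#' @export
make_templates <- function(metadata, lig_spec = ligand_spec(),
                           n_depths = 1L, n_rolls = 1L,
                           depth_range = c(8, 8)) {
  stopifnot(n_depths >= 1, n_rolls >= 1)
  depths <- if (n_depths == 1) mean(depth_range)
            else seq(depth_range[1], depth_range[2], length.out = n_depths)
  # rolls span [0, pi) with a small phase offset: the wall lattice is
  # symmetric under a pi rotation about the axis (even-count atom rings),
  # so rolls a and a + pi would yield exactly duplicated scores
  rolls <- pi * (seq_len(n_rolls) - 1) / n_rolls + pi / 7
  axis <- unit_vec(metadata$axis)
  base <- base_ligand_xyz(lig_spec)
  out <- list()
  k <- 0L
  for (d in depths) {
    for (th in rolls) {
      R <- rotation_about_axis(c(1, 0, 0), th)
      xyz <- base %*% t(R)
      # ligand frame x-axis onto the tunnel axis, then shift by depth
      if (!isTRUE(all.equal(axis, c(1, 0, 0)))) {
        v <- c(1, 0, 0)
        rot_axis <- pracma_cross(v, axis)
        ang <- acos(max(-1, min(1, sum(v * axis))))
        if (vec_norm(rot_axis) > 1e-9)
          xyz <- xyz %*% t(rotation_about_axis(rot_axis, ang))
      }
      xyz <- sweep(xyz, 2, metadata$center + d * axis, "+")
      k <- k + 1L
      out[[k]] <- make_synthetic_conformer(lig_spec, xyz, k)
    }
  }
  out
}

pracma_cross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Hollow-sphere calibration structure
#'
#' A closed shell of carbon pseudo-atoms whose probe-inflated surface
#' encloses a spherical cavity of the requested inner radius; used to
#' calibrate [detect_cavity()] against the analytic sphere volume.
#'
#' @param inner_radius Cavity radius, angstrom (default 6.2).
#' @param surface_spacing Approximate atom spacing on the shell.
#' @return A `ProteinStructure`.
#' @export
make_hollow_sphere <- function(inner_radius = 6.2, surface_spacing = 0.8) {
  R <- inner_radius + SYNTH_RINF
  n <- ceiling(4 * pi * R^2 / surface_spacing^2)
  # Fibonacci sphere: near-uniform point distribution on the shell
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  xyz <- R * cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
  atoms <- data.frame(
    type = "HETATM", serial = seq_len(n), name = "C", altloc = "",
    resname = "SPH", chain = "A", resseq = seq_len(n), insert = "",
    x = xyz[, 1], y = xyz[, 2], z = xyz[, 3], occupancy = 1.0, bfactor = 0.0,
    element = "C", polar_role = "none", stringsAsFactors = FALSE)
  new_protein_structure(atoms, id = "hollow_sphere")
}
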