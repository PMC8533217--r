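# Grid-occupancy pocket volumetrics: a cubic grid is anchored at the
# per-frame position of a reference atom (the substrate's 5th lipid-tail
# carbon in the tunnel measurement); grid points inside the spherical
# region that are not occluded by any atom (within vdW radius + probe
# radius) each contribute spacing^3 of free volume.

#' Define a spherical pocket region around a reference atom
#'
#' @param center An [atom_spec()] naming the atom the sphere follows, frame
#'   by frame.
#' @param radius Sphere radius in angstrom (default 6).
#' @param grid_spacing Grid spacing in angstrom (default 1; must not exceed
#'   the radius).
#' @param probe_radius Probe radius added to each occluder's vdW radius, in
#'   angstrom (default 1.4, a water-sized probe).
#' @param occluders Which atoms block volume: `"protein"` (default; standard
#'   amino-acid residues), `"all"` (every atom except the center atom
#'   itself), or an integer vector of atom indices.
#' @return Object of class `"pocket_region"`.
#' @export
pocket_region <- function(center, radius = 6, grid_spacing = 1,
                          probe_radius = 1.4, occluders = "protein") {
  stopifnot(inherits(center, "atom_spec"), radius > 0, grid_spacing > 0,
            probe_radius >= 0)
  if (grid_spacing > radius)
    stop("grid_spacing must not exceed the region radius", call. = FALSE)
  structure(list(center = center, radius = radius,
                 grid_spacing = grid_spacing, probe_radius = probe_radius,
                 occluders = occluders),
            class = "pocket_region")
}

region_grid_offsets <- function(region) {
  h <- region$grid_spacing
  k <- floor(region$radius / h)
  ax <- (-k:k) * h
  g <- as.matrix(expand.grid(x = ax, y = ax, z = ax))
  g[rowSums(g^2) <= region$radius^2 + 1e-9, , drop = FALSE]
}

occluder_indices <- function(topology, region, center_idx) {
  occ <- region$occluders
  if (is.numeric(occ)) return(setdiff(as.integer(occ), center_idx))
  if (identical(occ, "all")) return(setdiff(seq_len(nrow(topology)),
                                            center_idx))
  if (identical(occ, "protein"))
    return(setdiff(which(topology$residue_name %in% names(aa_three_letter())),
                   center_idx))
  stop("occluders must be \"protein\", \"all\" or atom indices",
       call. = FALSE)
}

pocket_volume_at <- function(center_xyz, occ_xyz, occ_r2, region) {
  g <- region_grid_offsets(region)
  free <- rep(TRUE, nrow(g))
  if (length(occ_r2)) {
    pts <- sweep(g, 2, center_xyz, "+")
    # only occluders that can reach the sphere matter
    reach <- region$radius + sqrt(max(occ_r2))
    d2c <- colSums((t(occ_xyz) - center_xyz)^2)
    near <- which(d2c <= reach^2)
    for (a in near) {
      d2 <- (pts[, 1] - occ_xyz[a, 1])^2 + (pts[, 2] - occ_xyz[a, 2])^2 +
        (pts[, 3] - occ_xyz[a, 3])^2
      free <- free & d2 > occ_r2[a]
      if (!any(free)) break
    }
  }
  sum(free) * region$grid_spacing^3
}

#' Unoccluded pocket volume in one frame
#'
#' @param coords `n_atoms x 3` coordinate matrix (angstrom).
#' @param topology Topology data frame matching `coords`.
#' @param region A [pocket_region()].
#' @param radii vdW radius table, by default [vdw_radii()].
#' @return Free volume in cubic angstrom; bounded by the analytic sphere
#'   volume from above and 0 from below.
#' @export
#' @examples
#' topo <- data.frame(serial = 1, atom_name = "C5", residue_name = "LIG",
#'                    residue_number = 1, chain_id = "A", element = "C")
#' xyz <- matrix(0, 1, 3)
#' pocket_volume(xyz, topo, pocket_region(atom_spec(1, "C5"),
#'                                        grid_spacing = 0.5))
pocket_volume <- function(coords, topology, region, radii = vdw_radii()) {
  stopifnot(inherits(region, "pocket_region"))
  ci <- resolve_atom(topology, region$center)
  occ <- occluder_indices(topology, region, ci)
  occ_r <- if (length(occ))
    element_radii(topology$element[occ], radii) + region$probe_radius
  else numeric()
  pocket_volume_at(coords[ci, ], coords[occ, , drop = FALSE], occ_r^2,
                   region)
}

#' Per-frame pocket volume series
#'
#' The grid is re-anchored on the center atom every frame, so the
#' measurement is invariant under rigid translation of the system.
#'
#' @param traj A [trajectory()].
#' @param region A [pocket_region()].
#' @param radii vdW radius table.
#' @return Data frame `(replicate_id, frame, volume_A3)`.
#' @export
volume_series <- function(traj, region, radii = vdw_radii()) {
  stopifnot(inherits(traj, "trajectory"))
  topo <- traj$topology
  ci <- resolve_atom(topo, region$center)
  occ <- occluder_indices(topo, region, ci)
  occ_r2 <- if (length(occ))
    (element_radii(topo$element[occ], radii) + region$probe_radius)^2
  else numeric()
  nf <- n_frames(traj)
  vol <- vapply(seq_len(nf), function(f) {
    xyz <- traj$coords[, , f]
    pocket_volume_at(xyz[ci, ], xyz[occ, , drop = FALSE], occ_r2, region)
  }, 0)
  data.frame(replicate_id = traj$replicate_id, frame = seq_len(nf),
             volume_A3 = vol)
}
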