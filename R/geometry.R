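# Core frame measurements. Distances/dihedrals are plain Euclidean geometry
# on whole (imaged) molecules: no minimum-image correction is applied, since
# all measured atoms sit within one molecule.

#' Interatomic distance within one frame
#'
#' @param coords `n_atoms x 3` coordinate matrix (angstrom).
#' @param i,j Distinct atom indices.
#' @return Distance in angstrom.
#' @export
#' @examples
#' xyz <- rbind(c(0, 0, 0), c(3, 4, 0))
#' atom_distance(xyz, 1, 2) # 5
atom_distance <- function(coords, i, j) {
  check_indices(coords, c(i, j))
  if (i == j) stop("distance requires two distinct atoms", call. = FALSE)
  sqrt(sum((coords[i, ] - coords[j, ])^2))
}

check_indices <- function(coords, idx) {
  if (any(idx < 1L | idx > nrow(coords)))
    stop(sprintf("atom index out of range (1..%d)", nrow(coords)),
         call. = FALSE)
  invisible(TRUE)
}

cross3 <- function(a, b) {
  # row-wise cross product for n x 3 matrices
  cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
        a[, 3] * b[, 1] - a[, 1] * b[, 3],
        a[, 1] * b[, 2] - a[, 2] * b[, 1])
}

dihedral_xyz <- function(p1, p2, p3, p4) {
  # vectorized IUPAC-signed torsion for stacked points (n x 3 matrices);
  # returns degrees in (-180, 180]
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  c12 <- cross3(b1, b2)
  c23 <- cross3(b2, b3)
  n12 <- sqrt(rowSums(c12^2))
  n23 <- sqrt(rowSums(c23^2))
  scale <- sqrt(rowSums(b1^2)) * sqrt(rowSums(b2^2))
  if (any(n12 <= 1e-9 * scale) || any(n23 <= 1e-9 * scale))
    stop("undefined torsion: three consecutive atoms are collinear",
         call. = FALSE)
  x <- rowSums(c12 * c23)
  y <- rowSums(cross3(c12, c23) * b2) / sqrt(rowSums(b2^2))
  chi <- atan2(y, x) * 180 / pi
  chi[chi <= -180] <- chi[chi <= -180] + 360
  chi
}

#' Proper dihedral angle within one frame
#'
#' IUPAC sign convention: cis = 0 degrees; sighting from atom j to atom k,
#' a clockwise rotation of the far bond relative to the near bond is
#' positive. Output lies in (-180, 180]. Reversing the atom order gives the
#' same angle; mirroring the coordinates negates it.
#'
#' @param coords `n_atoms x 3` coordinate matrix (angstrom).
#' @param i,j,k,l Four distinct atom indices along the torsion.
#' @return Torsion angle in degrees in (-180, 180].
#' @export
#' @examples
#' xyz <- rbind(c(0, 1, 0), c(0, 0, 0), c(1.5, 0, 0), c(1.5, -1, 0))
#' atom_dihedral(xyz, 1, 2, 3, 4) # 180 (anti)
atom_dihedral <- function(coords, i, j, k, l) {
  idx <- c(i, j, k, l)
  check_indices(coords, idx)
  if (anyDuplicated(idx)) stop("dihedral requires four distinct atoms",
                               call. = FALSE)
  dihedral_xyz(coords[i, , drop = FALSE], coords[j, , drop = FALSE],
               coords[k, , drop = FALSE], coords[l, , drop = FALSE])
}

# -- measurement specs -------------------------------------------------------

#' Define a labelled distance pair
#'
#' @param label Series label, e.g. `"Gln147-Trp153"`.
#' @param a,b [atom_spec()]s of the two atoms.
#' @return An object of class `"distance_pair"`.
#' @export
distance_pair <- function(label, a, b) {
  stopifnot(inherits(a, "atom_spec"), inherits(b, "atom_spec"))
  if (identical(unclass(a), unclass(b)))
    stop("distance pair needs two distinct atoms", call. = FALSE)
  structure(list(label = label, a = a, b = b), class = "distance_pair")
}

#' Define a labelled four-atom torsion
#'
#' @param label Series label, e.g. `"C8-C9-C10-C11"`.
#' @param atoms List of four [atom_spec()]s in torsion order.
#' @return An object of class `"dihedral_quad"`.
#' @export
dihedral_quad <- function(label, atoms) {
  stopifnot(length(atoms) == 4,
            all(vapply(atoms, inherits, TRUE, "atom_spec")))
  if (anyDuplicated(vapply(atoms, format, "")))
    stop("dihedral requires four distinct atoms", call. = FALSE)
  structure(list(label = label, atoms = atoms), class = "dihedral_quad")
}

#' Measurement specs for the desaturase tunnel triad and substrate torsion
#'
#' The two hydrogen-bond distances that underlie the kinked substrate tunnel
#' (Gln147 O-epsilon-1 to the Trp153 indole H-epsilon-1, and Gln147
#' H-epsilon-22 to Thr261 O-gamma-1) plus the substrate's C8-C9-C10-C11
#' torsion, using PDB v3 atom names.
#'
#' @param ligand_residue Residue number carrying the ligand carbons.
#' @return List with elements `d1`, `d2` ([distance_pair()]) and `chi`
#'   ([dihedral_quad()]).
#' @export
tunnel_specs <- function(ligand_residue = 1L) {
  list(
    d1 = distance_pair("Gln147-Trp153",
                       atom_spec(147, "OE1"), atom_spec(153, "HE1")),
    d2 = distance_pair("Gln147-Thr261",
                       atom_spec(147, "HE22"), atom_spec(261, "OG1")),
    chi = dihedral_quad("C8-C9-C10-C11",
                        lapply(c("C8", "C9", "C10", "C11"),
                               function(a) atom_spec(ligand_residue, a))))
}

# -- series extraction -------------------------------------------------------

resolve_spec_indices <- function(topology, spec) {
  if (inherits(spec, "distance_pair"))
    c(resolve_atom(topology, spec$a), resolve_atom(topology, spec$b))
  else if (inherits(spec, "dihedral_quad"))
    vapply(spec$atoms, function(a) resolve_atom(topology, a), 0L)
  else stop("unknown spec type", call. = FALSE)
}

#' Extract per-frame observable series from a trajectory
#'
#' All specs are resolved against the topology before any frame is touched,
#' so an unresolvable atom fails fast. Distances are reported in angstrom,
#' torsions in degrees in (-180, 180].
#'
#' @param traj A [trajectory()].
#' @param specs List of [distance_pair()] and/or [dihedral_quad()] objects.
#' @return Long-format data frame with columns `replicate_id`, `frame`,
#'   `label`, `value`, frames in file order.
#' @export
extract_series <- function(traj, specs) {
  if (inherits(specs, c("distance_pair", "dihedral_quad")))
    specs <- list(specs)
  idx <- lapply(specs, function(s) resolve_spec_indices(traj$topology, s))
  nf <- n_frames(traj)
  out <- lapply(seq_along(specs), function(s) {
    ii <- idx[[s]]
    val <- if (length(ii) == 2L) {
      d <- traj$coords[ii[1], , ] - traj$coords[ii[2], , ]
      if (nf == 1L) d <- matrix(d, ncol = 1)
      sqrt(colSums(d^2))
    } else {
      p <- lapply(ii, function(a) t(matrix(traj$coords[a, , ], nrow = 3)))
      dihedral_xyz(p[[1]], p[[2]], p[[3]], p[[4]])
    }
    data.frame(replicate_id = traj$replicate_id, frame = seq_len(nf),
               label = specs[[s]]$label, value = val,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Pull one labelled series as a numeric vector
#'
#' @param series Long-format data frame from [extract_series()].
#' @param label Series label to select.
#' @return Numeric vector in frame order.
#' @export
series_values <- function(series, label) {
  v <- series$value[series$label == label]
  if (!length(v)) stop("no series labelled '", label, "'", call. = FALSE)
  v
}

# -- internal-coordinate chain placement ------------------------------------

#' Place an atom chain from internal coordinates
#'
#' Natural-extension reference frame (NeRF) construction: atom 1 at the
#' origin, atom 2 along +x, atom 3 in the xy-plane, and each later atom
#' placed from its bond length, bond angle and torsion. Measuring any
#' torsion of the placed chain with [atom_dihedral()] recovers the input to
#' better than 1e-6 degrees, which is what makes the synthetic trajectories'
#' emitted observables exact.
#'
#' @param bond_lengths `n-1` bond lengths in angstrom (all > 0).
#' @param bond_angles `n-2` bond angles in degrees, each strictly inside
#'   (0, 180).
#' @param torsions `n-3` proper torsions in degrees.
#' @return `n x 3` coordinate matrix.
#' @export
#' @examples
#' xyz <- place_chain(rep(1.53, 3), rep(111, 2), -60)
#' atom_dihedral(xyz, 1, 2, 3, 4) # -60
place_chain <- function(bond_lengths, bond_angles, torsions = numeric()) {
  n <- length(bond_lengths) + 1L
  stopifnot(n >= 2L, length(bond_angles) == max(n - 2L, 0L),
            length(torsions) == max(n - 3L, 0L))
  if (any(bond_lengths <= 0)) stop("bond lengths must be positive",
                                   call. = FALSE)
  if (length(bond_angles) && any(bond_angles <= 0 | bond_angles >= 180))
    stop("bond angles must lie strictly inside (0, 180) degrees",
         call. = FALSE)
  deg <- pi / 180
  xyz <- matrix(0, n, 3)
  xyz[2, ] <- c(bond_lengths[1], 0, 0)
  if (n >= 3L) {
    th <- bond_angles[1] * deg
    xyz[3, ] <- xyz[2, ] + bond_lengths[2] * c(-cos(th), sin(th), 0)
  }
  if (n >= 4L) {
    for (a in 4:n) {
      r <- bond_lengths[a - 1L]
      th <- bond_angles[a - 2L] * deg
      ph <- torsions[a - 3L] * deg
      A <- xyz[a - 3L, ]; B <- xyz[a - 2L, ]; C <- xyz[a - 1L, ]
      bc <- C - B; bc <- bc / sqrt(sum(bc^2))
      ab <- B - A
      nvec <- c(ab[2] * bc[3] - ab[3] * bc[2],
                ab[3] * bc[1] - ab[1] * bc[3],
                ab[1] * bc[2] - ab[2] * bc[1])
      nn <- sqrt(sum(nvec^2))
      if (nn < 1e-12) stop("degenerate geometry: collinear reference atoms",
                           call. = FALSE)
      nvec <- nvec / nn
      mvec <- c(nvec[2] * bc[3] - nvec[3] * bc[2],
                nvec[3] * bc[1] - nvec[1] * bc[3],
                nvec[1] * bc[2] - nvec[2] * bc[1])
      d <- r * c(-cos(th), sin(th) * cos(ph), sin(th) * sin(ph))
      xyz[a, ] <- C + d[1] * bc + d[2] * mvec + d[3] * nvec
    }
  }
  xyz
}
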