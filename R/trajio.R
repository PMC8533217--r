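#' @importFrom stats rnorm runif setNames integrate
#' @importFrom utils read.csv write.csv
NULL

# -- vdW radii ---------------------------------------------------------------

#' Default van der Waals radii
#'
#' Bondi-style radii (in angstrom) used by the pocket-volume module to decide
#' which grid points an atom occludes. Elements absent from the table fall
#' back to the carbon radius (1.70 A) with a warning.
#'
#' @return Named numeric vector of radii in angstrom.
#' @export
#' @examples
#' vdw_radii()[["O"]]
vdw_radii <- function() {
  c(H = 1.20, C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80, FE = 1.40)
}

#' Look up vdW radii for a vector of element symbols
#'
#' @param elements Character vector of element symbols (case-insensitive).
#' @param radii Named radius table, by default [vdw_radii()].
#' @return Numeric vector of radii in angstrom.
#' @export
element_radii <- function(elements, radii = vdw_radii()) {
  key <- toupper(trimws(elements))
  out <- unname(radii[key])
  missing <- is.na(out)
  if (any(missing)) {
    warning(sprintf(
      "no vdW radius for element(s) %s; falling back to 1.70 A",
      paste(unique(key[missing]), collapse = ", ")), call. = FALSE)
    out[missing] <- 1.70
  }
  out
}

# -- atom specs --------------------------------------------------------------

#' Specify an atom by residue number and atom name
#'
#' Atom addressing follows PDB v3 naming ("OE1", "HE1", "HE22", "OG1", ...),
#' the convention the deposited desaturase models use; Greek-letter names in
#' the structural literature (O-epsilon-1 etc.) map onto these.
#'
#' @param residue_number Integer residue number.
#' @param atom_name PDB atom name, e.g. `"OE1"`.
#' @param chain_id Optional single-character chain identifier, used to break
#'   ties when the same residue number occurs in several chains.
#' @return An object of class `"atom_spec"`.
#' @export
#' @examples
#' atom_spec(147, "OE1")
atom_spec <- function(residue_number, atom_name, chain_id = NULL) {
  stopifnot(length(residue_number) == 1, length(atom_name) == 1,
            nzchar(atom_name))
  structure(list(residue_number = as.integer(residue_number),
                 atom_name = as.character(atom_name),
                 chain_id = if (is.null(chain_id)) NULL else as.character(chain_id)),
            class = "atom_spec")
}

#' @export
format.atom_spec <- function(x, ...) {
  sprintf("%s%d/%s", if (is.null(x$chain_id)) "" else paste0(x$chain_id, ":"),
          x$residue_number, x$atom_name)
}

#' @export
print.atom_spec <- function(x, ...) {
  cat("<atom_spec>", format(x), "\n")
  invisible(x)
}

#' Resolve an atom spec to an atom index
#'
#' @param topology A topology data frame (see [read_structure()]).
#' @param spec An [atom_spec()].
#' @return The (1-based) index of the unique matching atom.
#' @export
resolve_atom <- function(topology, spec) {
  stopifnot(inherits(spec, "atom_spec"))
  hit <- topology$residue_number == spec$residue_number &
    topology$atom_name == spec$atom_name
  if (!is.null(spec$chain_id))
    hit <- hit & topology$chain_id == spec$chain_id
  idx <- which(hit)
  if (length(idx) == 0L)
    stop(sprintf("no atom matches spec %s", format(spec)), call. = FALSE)
  if (length(idx) > 1L)
    stop(sprintf(
      "spec %s is ambiguous (%d matches, chains %s); add chain_id",
      format(spec), length(idx),
      paste(unique(topology$chain_id[idx]), collapse = ",")), call. = FALSE)
  idx
}

# -- trajectory container ----------------------------------------------------

#' Construct a trajectory object
#'
#' A trajectory couples a topology (one row per atom: serial, atom_name,
#' residue_name, residue_number, chain_id, element) with an ordered stack of
#' coordinate frames stored as an `n_atoms x 3 x n_frames` array in angstrom.
#'
#' @param topology Data frame with columns `serial`, `atom_name`,
#'   `residue_name`, `residue_number`, `chain_id`, `element`.
#' @param coords Numeric array `n_atoms x 3 x n_frames` (a single
#'   `n_atoms x 3` matrix is promoted to one frame).
#' @param replicate_id Character label identifying the replicate simulation.
#' @return An object of class `"trajectory"`.
#' @export
trajectory <- function(topology, coords, replicate_id = "rep1") {
  if (is.matrix(coords)) coords <- array(coords, c(dim(coords), 1L))
  stopifnot(is.array(coords), length(dim(coords)) == 3L, dim(coords)[2] == 3L)
  req <- c("serial", "atom_name", "residue_name", "residue_number",
           "chain_id", "element")
  miss <- setdiff(req, names(topology))
  if (length(miss))
    stop("topology lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (anyDuplicated(topology$serial))
    stop("topology atom serials are not unique", call. = FALSE)
  if (nrow(topology) != dim(coords)[1])
    stop(sprintf("topology has %d atoms but coords %d",
                 nrow(topology), dim(coords)[1]), call. = FALSE)
  if (dim(coords)[3] < 1L) stop("trajectory needs at least one frame",
                                call. = FALSE)
  if (!all(is.finite(coords))) stop("non-finite coordinates", call. = FALSE)
  structure(list(topology = topology, coords = coords,
                 replicate_id = as.character(replicate_id)),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("<trajectory> %d atoms, %d frame(s), replicate '%s'\n",
              n_atoms(x), n_frames(x), x$replicate_id))
  invisible(x)
}

#' Number of frames in a trajectory
#' @param traj A [trajectory()].
#' @return Integer frame count.
#' @export
n_frames <- function(traj) dim(traj$coords)[3]

#' Number of atoms in a trajectory
#' @param traj A [trajectory()].
#' @return Integer atom count.
#' @export
n_atoms <- function(traj) dim(traj$coords)[1]

#' Extract one frame's coordinates
#' @param traj A [trajectory()].
#' @param i Frame index (1-based).
#' @return `n_atoms x 3` coordinate matrix in angstrom.
#' @export
frame_coords <- function(traj, i) {
  if (i < 1 || i > n_frames(traj)) stop("frame index out of range",
                                        call. = FALSE)
  traj$coords[, , i, drop = TRUE]
}

# -- PDB reading -------------------------------------------------------------

topology_from_pdb <- function(pdb) {
  a <- pdb$atom
  elem <- trimws(a$elesy)
  blank <- is.na(elem) | !nzchar(elem)
  if (any(blank)) # infer from the first letter of the atom name
    elem[blank] <- sub("^[0-9]*([A-Za-z]).*", "\\1", trimws(a$elety[blank]))
  data.frame(serial = a$eleno,
             atom_name = trimws(a$elety),
             residue_name = trimws(a$resid),
             residue_number = a$resno,
             chain_id = ifelse(is.na(a$chain), "", a$chain),
             element = toupper(elem),
             b_factor = ifelse(is.na(a$b), 0, a$b),
             stringsAsFactors = FALSE)
}

#' Read a (possibly multi-model) PDB structure as a trajectory
#'
#' Each MODEL record becomes one frame; a file without MODEL records yields a
#' single-frame trajectory. Alternate-location indicators other than 'A' or
#' blank are dropped (count reported), so repeated reads of crystallographic
#' files are deterministic.
#'
#' @param path Path to a PDB file.
#' @param replicate_id Replicate label attached to the result.
#' @return A [trajectory()].
#' @export
read_structure <- function(path, replicate_id = basename(path)) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  check_pdb_lines(path)
  pdb <- tryCatch(
    suppressWarnings(bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)),
    error = function(e) stop(sprintf("failed to parse PDB '%s': %s",
                                     path, conditionMessage(e)),
                             call. = FALSE))
  alt <- trimws(pdb$atom$alt)
  drop <- !is.na(alt) & nzchar(alt) & alt != "A"
  if (any(drop)) {
    message(sprintf("dropping %d alternate-location atoms (altloc != 'A')",
                    sum(drop)))
    pdb <- bio3d::trim.pdb(pdb, inds = list(
      atom = which(!drop), xyz = bio3d::atom2xyz(which(!drop))))
  }
  topo <- topology_from_pdb(pdb)
  xyz <- pdb$xyz
  if (!is.matrix(xyz)) xyz <- matrix(xyz, nrow = 1)
  if (ncol(xyz) != 3 * nrow(topo))
    stop("inconsistent atom count across models", call. = FALSE)
  nf <- nrow(xyz)
  coords <- array(NA_real_, c(nrow(topo), 3, nf))
  for (f in seq_len(nf))
    coords[, , f] <- matrix(xyz[f, ], ncol = 3, byrow = TRUE)
  trajectory(topo, coords, replicate_id)
}

check_pdb_lines <- function(path) {
  lines <- readLines(path, warn = FALSE)
  rec <- grepl("^(ATOM  |HETATM)", lines)
  if (any(rec)) {
    short <- rec & nchar(lines) < 54
    coords <- substr(lines, 31, 54)
    badnum <- rec & !short &
      is.na(suppressWarnings(as.numeric(substr(coords, 1, 8)))) |
      rec & !short &
      is.na(suppressWarnings(as.numeric(substr(coords, 9, 16)))) |
      rec & !short &
      is.na(suppressWarnings(as.numeric(substr(coords, 17, 24))))
    bad <- which(short | badnum)
    if (length(bad))
      stop(sprintf("malformed ATOM/HETATM record at line %d of '%s'",
                   bad[1], path), call. = FALSE)
  }
  invisible(TRUE)
}

# -- PDB writing -------------------------------------------------------------

#' Write a trajectory as a (multi-model) PDB file
#'
#' Coordinates are written at the format's fixed-point precision (1e-3 A),
#' one MODEL per frame, so a write/read round trip preserves names, residue
#' numbers and coordinates to that precision.
#'
#' @param traj A [trajectory()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_structure <- function(traj, path) {
  topo <- traj$topology
  nf <- n_frames(traj)
  con <- file(path, "w")
  on.exit(close(con))
  is_het <- !(topo$residue_name %in% names(aa_three_letter()))
  for (f in seq_len(nf)) {
    if (nf > 1L) writeLines(sprintf("MODEL     %4d", f), con)
    xyz <- traj$coords[, , f]
    lines <- sprintf(
      "%-6s%5d %-4s %-4s%1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
      ifelse(is_het, "HETATM", "ATOM"),
      topo$serial %% 100000L,
      formatC(ifelse(nchar(topo$atom_name) < 4,
                     paste0(" ", topo$atom_name), topo$atom_name),
              width = -4),
      topo$residue_name,
      ifelse(nzchar(topo$chain_id), topo$chain_id, " "),
      topo$residue_number %% 10000L,
      xyz[, 1], xyz[, 2], xyz[, 3],
      1.00,
      if ("b_factor" %in% names(topo)) topo$b_factor else 0,
      topo$element)
    writeLines(lines, con)
    if (nf > 1L) writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

aa_three_letter <- function() {
  nm <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS",
          "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP",
          "TYR", "VAL", "HSD", "HSE", "HSP")
  setNames(rep(TRUE, length(nm)), nm)
}

# -- DCD ---------------------------------------------------------------------

#' Write coordinate frames to a CHARMM-format DCD file
#'
#' Single-precision binary trajectory format as produced by CHARMM/NAMD.
#' Coordinates are stored as 32-bit floats, so a round trip is exact only to
#' about 1e-4 A at protein-scale magnitudes.
#'
#' @param coords `n_atoms x 3 x n_frames` array in angstrom.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_dcd <- function(coords, path) {
  if (is.matrix(coords)) coords <- array(coords, c(dim(coords), 1L))
  stopifnot(length(dim(coords)) == 3L, dim(coords)[2] == 3L)
  na <- dim(coords)[1]; nf <- dim(coords)[3]
  if (nf < 1L) stop("no frames to write", call. = FALSE)
  con <- file(path, "wb")
  on.exit(close(con))
  icntrl <- integer(20)
  icntrl[1] <- nf      # frames in file
  icntrl[2] <- 1L      # first step
  icntrl[3] <- 1L      # save interval
  icntrl[4] <- nf      # last step
  icntrl[20] <- 24L    # CHARMM version stamp
  writeBin(84L, con, size = 4)
  writeChar("CORD", con, nchars = 4, eos = NULL)
  writeBin(icntrl, con, size = 4)
  writeBin(84L, con, size = 4)
  title <- formatC("Written by mdscape", width = -80)
  writeBin(4L + 80L, con, size = 4)
  writeBin(1L, con, size = 4)
  writeChar(title, con, nchars = 80, eos = NULL)
  writeBin(4L + 80L, con, size = 4)
  writeBin(4L, con, size = 4)
  writeBin(na, con, size = 4)
  writeBin(4L, con, size = 4)
  reclen <- 4L * na
  for (f in seq_len(nf)) {
    for (ax in 1:3) {
      writeBin(reclen, con, size = 4)
      writeBin(as.numeric(coords[, ax, f]), con, size = 4)
      writeBin(reclen, con, size = 4)
    }
  }
  invisible(path)
}

#' Read a trajectory from a topology file plus a frame stream
#'
#' @param topology_path PDB file defining atoms and their order.
#' @param frames_path DCD or multi-model PDB file of frames.
#' @param format `"auto"` (by extension), `"dcd"` or `"pdb"`.
#' @param replicate_id Replicate label.
#' @return A [trajectory()].
#' @export
read_trajectory <- function(topology_path, frames_path,
                            format = c("auto", "dcd", "pdb"),
                            replicate_id = basename(frames_path)) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.dcd$", frames_path, ignore.case = TRUE))
      "dcd" else "pdb"
  topo_traj <- read_structure(topology_path)
  topo <- topo_traj$topology
  if (format == "dcd") {
    if (file.size(frames_path) == 0)
      stop("empty frames file: ", frames_path, call. = FALSE)
    xyz <- tryCatch(bio3d::read.dcd(frames_path, verbose = FALSE),
                    error = function(e)
                      stop(sprintf("failed to parse DCD '%s': %s", frames_path,
                                   conditionMessage(e)), call. = FALSE))
    if (!is.matrix(xyz)) xyz <- matrix(xyz, nrow = 1)
    if (ncol(xyz) != 3L * nrow(topo))
      stop(sprintf("DCD atom count (%d) does not match topology (%d)",
                   ncol(xyz) %/% 3L, nrow(topo)), call. = FALSE)
    nf <- nrow(xyz)
    coords <- array(NA_real_, c(nrow(topo), 3, nf))
    for (f in seq_len(nf))
      coords[, , f] <- matrix(xyz[f, ], ncol = 3, byrow = TRUE)
  } else {
    ft <- read_structure(frames_path)
    if (n_atoms(ft) != nrow(topo))
      stop(sprintf("frame atom count (%d) does not match topology (%d)",
                   n_atoms(ft), nrow(topo)), call. = FALSE)
    coords <- ft$coords
  }
  trajectory(topo, coords, replicate_id)
}

#' Write a trajectory as topology + frame files
#'
#' @param traj A [trajectory()].
#' @param topology_path Output PDB path for the topology (first frame).
#' @param frames_path Output path for all frames (DCD or multi-model PDB).
#' @param format `"dcd"` or `"pdb"`.
#' @return Invisible list of the two paths.
#' @export
write_trajectory <- function(traj, topology_path, frames_path,
                             format = c("dcd", "pdb")) {
  format <- match.arg(format)
  write_structure(trajectory(traj$topology, traj$coords[, , 1, drop = FALSE],
                             traj$replicate_id), topology_path)
  if (format == "dcd") write_dcd(traj$coords, frames_path)
  else write_structure(traj, frames_path)
  invisible(list(topology = topology_path, frames = frames_path))
}
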