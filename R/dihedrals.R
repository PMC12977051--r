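# chi1 is the N-CA-CB-gamma torsion; the gamma heavy atom depends on the
# residue type.  Gly and Ala have no chi1 and are excluded.
.chi1_gamma <- c(
  ARG = "CG", ASN = "CG", ASP = "CG", CYS = "SG", GLN = "CG", GLU = "CG",
  HIS = "CG", HSD = "CG", HSE = "CG", HSP = "CG", HID = "CG", HIE = "CG",
  HIP = "CG", ILE = "CG1", LEU = "CG", LYS = "CG", MET = "CG", PHE = "CG",
  PRO = "CG", SER = "OG", THR = "OG1", TRP = "CG", TYR = "CG", VAL = "CG1"
)

# glycosidic quadruple: O4'-C1'-N9-C4 for purines, O4'-C1'-N1-C2 for
# pyrimidines; resolves syn vs anti base orientation
.purines <- c("A", "G", "DA", "DG", "ADE", "GUA", "RA", "RG")
.pyrimidines <- c("C", "T", "U", "DC", "DT", "DU", "CYT", "THY", "URA",
                  "RC", "RU")

#' Wrap a signed dihedral angle onto [0, 360)
#'
#' Raw dihedrals come out of geometry code as signed degrees in
#' \code{(-180, 180]}; negative angles are replaced by their secondary angle
#' (\code{+ 360}) so the whole series lives on \code{[0, 360)}, the range the
#' state bins are defined on.  The map is a bijection from \code{(-180, 180]}
#' onto \code{[0, 360)} (180 maps to 180, -180 is accepted and also maps
#' to 180).
#'
#' @param raw_angle numeric, degrees in \code{[-180, 180]}.
#' @return degrees in \code{[0, 360)}; vectorized.
#' @examples
#' wrap_angle(-60)  # 300
#' @export
wrap_angle <- function(raw_angle) {
  if (anyNA(raw_angle) || any(!is.finite(raw_angle)))
    stop("angle must be finite")
  if (any(raw_angle < -180 | raw_angle > 180))
    stop("raw dihedral must lie in [-180, 180]")
  out <- ifelse(raw_angle < 0, raw_angle + 360, raw_angle)
  out[out >= 360] <- out[out >= 360] - 360
  out
}

#' Per-residue dihedral time series
#'
#' @param angles numeric vector of angles in degrees, \code{[0, 360)}
#'   (\code{NA} allowed for geometrically undefined frames).
#' @param frame_interval time between frames (picoseconds for MD input).
#' @param key residue identifier \code{"SEG:RESNAME:RESID"}.
#' @param atom_quadruple the four atom names defining the torsion.
#' @return object of class \code{"dihedral_series"}.
#' @export
dihedral_series <- function(angles, frame_interval = 1, key = NA_character_,
                            atom_quadruple = rep(NA_character_, 4L)) {
  angles <- as.numeric(angles)
  ok <- !is.na(angles)
  if (any(angles[ok] < 0 | angles[ok] >= 360))
    stop("angles must lie in [0, 360)")
  if (frame_interval <= 0) stop("frame_interval must be positive")
  structure(list(angles = angles, frame_interval = frame_interval,
                 key = as.character(key),
                 atom_quadruple = as.character(atom_quadruple),
                 n_frames = length(angles)),
            class = "dihedral_series")
}

#' @export
print.dihedral_series <- function(x, ...) {
  cat(sprintf("<dihedral_series> %s (%s): %d frames, dt = %g\n", x$key,
              paste(x$atom_quadruple, collapse = "-"), x$n_frames,
              x$frame_interval))
  invisible(x)
}

# unify primed / apostrophe / star sugar-atom dialects on the apostrophe form
.normalize_atom <- function(name) {
  name <- gsub("′", "'", name, fixed = TRUE)
  gsub("*", "'", name, fixed = TRUE)
}

.residue_key <- function(seg, resname, resid) {
  seg[is.na(seg) | seg == ""] <- "-"
  sprintf("%s:%s:%d", seg, resname, as.integer(resid))
}

# load topology (+ optional trajectory) into a pdb object and an
# n_frames x 3*natom coordinate matrix
.load_coords <- function(topology, trajectory = NULL) {
  pdb <- if (inherits(topology, "pdb")) topology
         else bio3d::read.pdb(topology, multi = TRUE)
  xyz <- if (is.null(trajectory)) {
    pdb$xyz
  } else if (is.matrix(trajectory) || inherits(trajectory, "xyz")) {
    trajectory
  } else if (grepl("\\.dcd$", trajectory, ignore.case = TRUE)) {
    bio3d::read.dcd(trajectory, verbose = FALSE)
  } else {
    bio3d::read.pdb(trajectory, multi = TRUE)$xyz
  }
  xyz <- as.matrix(xyz)
  if (ncol(xyz) != 3L * nrow(pdb$atom))
    stop("trajectory atom count does not match the topology")
  list(pdb = pdb, xyz = xyz)
}

# torsion of one atom quadruple across all frames, signed degrees
.torsion_frames <- function(xyz, idx4) {
  cols <- as.vector(vapply(idx4, function(i) (3L * (i - 1L) + 1L):(3L * i),
                           integer(3)))
  apply(xyz[, cols, drop = FALSE], 1L, function(v)
    bio3d::torsion.xyz(v, atm.inc = 4L))
}

.extract_series <- function(topology, trajectory, want, stride,
                            frame_interval, polymer) {
  lc <- .load_coords(topology, trajectory)
  atoms <- lc$pdb$atom
  atoms$name_n <- .normalize_atom(atoms$elety)
  seg <- if (!is.null(atoms$chain) && !all(is.na(atoms$chain))) atoms$chain
         else atoms$segid
  rid <- paste(seg, atoms$resid, atoms$resno)
  frames <- seq(1L, nrow(lc$xyz), by = stride)
  out <- list()
  for (ur in unique(rid)) {
    sel <- which(rid == ur)
    resname <- atoms$resid[sel[1L]]
    quad <- want(resname)
    if (is.null(quad)) next                       # residue type not analyzed
    idx4 <- sel[match(quad, atoms$name_n[sel])]
    key <- .residue_key(seg[sel[1L]], resname, atoms$resno[sel[1L]])
    if (anyNA(idx4)) {
      warning(sprintf("%s: missing atom(s) %s; residue skipped", key,
                      paste(quad[is.na(match(quad, atoms$name_n[sel]))],
                            collapse = ", ")), call. = FALSE)
      next
    }
    raw <- .torsion_frames(lc$xyz[frames, , drop = FALSE], idx4)
    ang <- rep(NA_real_, length(raw))
    ok <- is.finite(raw)
    ang[ok] <- wrap_angle(raw[ok])
    out[[key]] <- dihedral_series(ang, frame_interval * stride, key, quad)
  }
  out
}

#' Extract chi1 side-chain dihedral series from a trajectory
#'
#' Computes the first side-chain torsion (N-CA-CB-gamma) for every residue
#' that has one; glycine and alanine, which lack a chi1, are skipped, as are
#' residues with missing atoms (with a warning).  Angles are wrapped onto
#' \code{[0, 360)}.  Frames with a geometrically undefined torsion yield
#' \code{NA} and are handled downstream by [discretize_angles()].
#'
#' @param topology a \code{bio3d} \code{pdb} object or path to a PDB file.
#' @param trajectory optional coordinates: a DCD path, a multi-model PDB
#'   path, or an \code{n_frames x 3*natom} xyz matrix.  \code{NULL} uses the
#'   topology's own (possibly multi-model) coordinates.
#' @param stride keep every \code{stride}-th frame; \code{frame_interval} is
#'   scaled accordingly.
#' @param frame_interval time between stored trajectory frames (picoseconds).
#' @return named list of [dihedral_series], one per retained residue, keyed
#'   \code{"SEG:RESNAME:RESID"}.
#' @export
extract_chi1 <- function(topology, trajectory = NULL, stride = 1L,
                         frame_interval = 1) {
  want <- function(resname) {
    if (resname %in% c("GLY", "ALA")) return(NULL)
    g <- .chi1_gamma[resname]
    if (is.na(g)) return(NULL)
    c("N", "CA", "CB", unname(g))
  }
  .extract_series(topology, trajectory, want, stride, frame_interval,
                  "protein")
}

#' Extract glycosidic base-sugar dihedral series for DNA
#'
#' The glycosidic torsion distinguishing syn from anti base orientation:
#' O4'-C1'-N9-C4 for purines (A, G), O4'-C1'-N1-C2 for pyrimidines (C, T).
#' Primed, apostrophe and star sugar-atom naming dialects are accepted.
#' Unknown base names are skipped with a warning.
#'
#' @inheritParams extract_chi1
#' @return named list of [dihedral_series].
#' @export
extract_glycosidic <- function(topology, trajectory = NULL, stride = 1L,
                               frame_interval = 1) {
  # amino acids, water and common ions are silently ignored so mixed
  # protein-DNA topologies can be passed whole; anything else that is not a
  # recognized base is reported
  silent <- c(names(.chi1_gamma), "GLY", "ALA", "HOH", "WAT", "TIP3", "TIP4",
              "SPC", "SOL", "NA", "CL", "K", "MG", "SOD", "CLA", "POT", "CAL")
  unknown <- character(0)
  want <- function(resname) {
    if (resname %in% .purines) c("O4'", "C1'", "N9", "C4")
    else if (resname %in% .pyrimidines) c("O4'", "C1'", "N1", "C2")
    else {
      if (!(resname %in% silent)) unknown <<- c(unknown, resname)
      NULL
    }
  }
  res <- .extract_series(topology, trajectory, want, stride, frame_interval,
                         "dna")
  if (length(unknown))
    warning("unknown base name(s) skipped: ",
            paste(unique(unknown), collapse = ", "), call. = FALSE)
  res
}
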