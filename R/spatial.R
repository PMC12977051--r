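#' Per-residue reference positions
#'
#' One 3D point per residue, in nanometres, from a reference structure:
#' by default the center of geometry of the residue's dihedral quadruple
#' atoms averaged over the supplied frames (time-averaged structure), with
#' Calpha or C1' selectable instead.  Coordinates in PDB files are in
#' Angstrom and are divided by 10.
#'
#' @param topology a \code{bio3d} \code{pdb} object or PDB path.
#' @param trajectory optional coordinates as in [extract_chi1()]; positions
#'   are averaged over its frames.  \code{NULL} uses the topology's own
#'   coordinates.
#' @param series optional named list of [dihedral_series]; when given (and
#'   \code{point = "quadruple"}), positions are computed for exactly those
#'   residues from their recorded atom quadruples.
#' @param point \code{"quadruple"} (center of geometry of the four torsion
#'   atoms), \code{"CA"}, or \code{"C1'"}.
#' @return matrix \code{n x 3} in nm with residue-key rownames.
#' @export
residue_positions <- function(topology, trajectory = NULL, series = NULL,
                              point = c("quadruple", "CA", "C1'")) {
  point <- match.arg(point)
  lc <- .load_coords(topology, trajectory)
  atoms <- lc$pdb$atom
  atoms$name_n <- .normalize_atom(atoms$elety)
  seg <- if (!is.null(atoms$chain) && !all(is.na(atoms$chain))) atoms$chain
         else atoms$segid
  keyv <- .residue_key(seg, atoms$resid, atoms$resno)
  mean_xyz <- colMeans(matrix(lc$xyz, nrow = nrow(lc$xyz)))
  coord <- matrix(mean_xyz, ncol = 3L, byrow = TRUE)  # natom x 3, Angstrom
  pos_of <- function(key) {
    sel <- which(keyv == key)
    if (!length(sel)) return(rep(NA_real_, 3L))
    use <- if (point == "quadruple" && !is.null(series) && key %in% names(series)) {
      sel[match(series[[key]]$atom_quadruple, atoms$name_n[sel])]
    } else if (point %in% c("CA", "C1'")) {
      sel[atoms$name_n[sel] == point]
    } else sel   # whole residue fallback
    use <- use[!is.na(use)]
    if (!length(use)) return(rep(NA_real_, 3L))
    colMeans(coord[use, , drop = FALSE])
  }
  keys <- if (!is.null(series)) names(series) else unique(keyv)
  out <- t(vapply(keys, pos_of, numeric(3))) / 10   # Angstrom -> nm
  colnames(out) <- c("x", "y", "z")
  out
}

#' Fraction of correlated pairs versus spatial separation
#'
#' Bins residue pairs by their spatial separation and reports, per bin, the
#' fraction whose coupling reaches the threshold.  The distance-0 bin is the
#' diagonal: each residue against itself, i.e. the fraction of residues with
#' dynamical memory at or above the threshold.  Conditional activity is
#' directional, so ordered pairs are counted (\code{symmetric = FALSE});
#' mutual information is symmetric and counts each unordered pair once
#' (\code{symmetric = TRUE}).  Bins containing no pair get \code{NA}, not 0.
#'
#' @param matrix square coupling matrix (activity or MI) with residue-key
#'   dimnames.
#' @param positions \code{n x 3} matrix in nm, rownames covering the
#'   matrix's residues (from [residue_positions()]).
#' @param threshold coupling value at or above which a pair counts as
#'   correlated.
#' @param bin_width,max_dist distance bins \code{[0, bin_width), ...} up to
#'   \code{max_dist}, in nm; bin 0 is the self-pair bin.
#' @param symmetric count unordered pairs once (for MI).
#' @return data.frame: \code{bin_mid_nm}, \code{fraction}, \code{n_pairs},
#'   \code{n_correlated}; first row is the distance-0 (diagonal) bin.
#' @export
fraction_correlated <- function(matrix, positions, threshold = 2,
                                bin_width = 0.5, max_dist = 10,
                                symmetric = FALSE) {
  M <- as.matrix(matrix)
  keys <- rownames(M)
  if (is.null(keys) || !all(keys %in% rownames(positions)))
    stop("positions must cover every residue of the matrix")
  P <- positions[keys, , drop = FALSE]
  ok <- stats::complete.cases(P)
  M <- M[ok, ok, drop = FALSE]; P <- P[ok, , drop = FALSE]
  n <- nrow(M)
  D <- as.matrix(stats::dist(P))
  edges <- seq(0, max_dist, by = bin_width)
  mids <- edges[-length(edges)] + bin_width / 2
  frac <- np <- nc <- rep(NA_real_, length(mids) + 1L)
  # distance-0 bin: the diagonal (dynamical memory)
  dg <- diag(M)
  np[1L] <- sum(!is.na(dg)); nc[1L] <- sum(dg >= threshold, na.rm = TRUE)
  frac[1L] <- if (np[1L] > 0) nc[1L] / np[1L] else NA_real_
  pair <- if (symmetric) upper.tri(M) else upper.tri(M) | lower.tri(M)
  db <- findInterval(D[pair], edges, rightmost.closed = FALSE)
  vals <- M[pair]
  for (b in seq_along(mids)) {
    in_bin <- db == b & !is.na(vals)
    np[b + 1L] <- sum(in_bin)
    if (np[b + 1L] > 0) {
      nc[b + 1L] <- sum(vals[in_bin] >= threshold)
      frac[b + 1L] <- nc[b + 1L] / np[b + 1L]
    }
  }
  data.frame(bin_mid_nm = c(0, mids), fraction = frac, n_pairs = np,
             n_correlated = nc)
}

#' Distance profile of kinetic vs entropic correlation
#'
#' The fraction of kinetically correlated pairs (conditional activity at or
#' above \code{ca_threshold}) and of entropically correlated pairs (MI at or
#' above a fraction of its own off-diagonal maximum) per distance bin,
#' averaged over replicas with the standard error of the mean.  The MI
#' threshold mirrors the conditional-activity rule — the activity cutoff of
#' 2 corresponds to about 20\% of the highest inter-residue activity, and the
#' same fractional rule (\code{mi_threshold_frac}) is applied to MI.
#'
#' @param ca_matrices list (one per replica) of activity matrices or
#'   \code{"condact"} fits.
#' @param mi_matrices optional list of MI matrices, same replicas.
#' @param positions as in [fraction_correlated()].
#' @param ca_threshold activity cutoff (dimensionless).
#' @param mi_threshold_frac MI cutoff as a fraction of the maximum
#'   off-diagonal MI (per replica).
#' @param bin_width,max_dist bins in nm.
#' @return object of class \code{"distance_profile"}: data.frame with
#'   \code{bin_mid_nm}, \code{fraction_CA}, \code{sem_CA}, and when MI is
#'   supplied \code{fraction_MI}, \code{sem_MI}; plus \code{n_pairs} of the
#'   first replica.
#' @export
distance_profile <- function(ca_matrices, positions, mi_matrices = NULL,
                             ca_threshold = 2, mi_threshold_frac = 0.2,
                             bin_width = 0.5, max_dist = 10) {
  if (inherits(ca_matrices, "condact") || is.matrix(ca_matrices))
    ca_matrices <- list(ca_matrices)
  getM <- function(x) if (inherits(x, "condact")) x$activity else as.matrix(x)
  fr_ca <- lapply(ca_matrices, function(x)
    fraction_correlated(getM(x), positions, ca_threshold, bin_width, max_dist,
                        symmetric = FALSE))
  agg <- function(frs) {
    mat <- vapply(frs, `[[`, numeric(nrow(frs[[1L]])), "fraction")
    mat <- matrix(mat, nrow = nrow(frs[[1L]]))
    m <- apply(mat, 1L, function(v) if (all(is.na(v))) NA_real_
                                    else mean(v, na.rm = TRUE))
    s <- apply(mat, 1L, function(v) {
      v <- v[!is.na(v)]
      if (length(v) < 2L) NA_real_ else stats::sd(v) / sqrt(length(v))
    })
    list(mean = m, sem = s)
  }
  a <- agg(fr_ca)
  out <- data.frame(bin_mid_nm = fr_ca[[1L]]$bin_mid_nm,
                    fraction_CA = a$mean, sem_CA = a$sem,
                    n_pairs = fr_ca[[1L]]$n_pairs)
  if (!is.null(mi_matrices)) {
    if (is.matrix(mi_matrices)) mi_matrices <- list(mi_matrices)
    fr_mi <- lapply(mi_matrices, function(M) {
      M <- as.matrix(M)
      off <- M; diag(off) <- NA
      thr <- mi_threshold_frac * max(off, na.rm = TRUE)
      fraction_correlated(M, positions, thr, bin_width, max_dist,
                          symmetric = TRUE)
    })
    b <- agg(fr_mi)
    out$fraction_MI <- b$mean
    out$sem_MI <- b$sem
  }
  attr(out, "thresholds") <- list(ca = ca_threshold,
                                  mi_frac = mi_threshold_frac)
  attr(out, "pair_counting") <- c(CA = "ordered", MI = "unordered")
  class(out) <- c("distance_profile", "data.frame")
  out
}

#' @export
plot.distance_profile <- function(x, ...) {
  graphics::plot(x$bin_mid_nm, x$fraction_CA, type = "b", pch = 16,
                 xlab = "separation (nm)", ylab = "fraction correlated",
                 ylim = c(0, max(c(x$fraction_CA, x$fraction_MI, 0.05),
                                 na.rm = TRUE)), ...)
  ok <- !is.na(x$sem_CA)
  if (any(ok))
    graphics::arrows(x$bin_mid_nm[ok], x$fraction_CA[ok] - x$sem_CA[ok],
                     x$bin_mid_nm[ok], x$fraction_CA[ok] + x$sem_CA[ok],
                     angle = 90, code = 3, length = 0.03)
  if (!is.null(x$fraction_MI)) {
    graphics::lines(x$bin_mid_nm, x$fraction_MI, type = "b", pch = 1,
                    col = "grey40")
    graphics::legend("topright", c("conditional activity", "mutual information"),
                     pch = c(16, 1), col = c("black", "grey40"), bty = "n")
  }
  invisible(x)
}
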