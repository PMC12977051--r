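#' Write / read a dihedral angle matrix as delimited text
#'
#' Tab-separated matrix, one row per frame and one column per residue, with
#' a header row of residue keys (\code{"SEG:RESNAME:RESID"}).  A JSON
#' sidecar (\code{<path>.json}) carries the frame interval and the atom
#' quadruples so the series round-trip losslessly.
#'
#' @param series named list of [dihedral_series] with equal frame counts.
#' @param path output file; the sidecar goes to \code{paste0(path, ".json")}.
#' @return \code{path}, invisibly.
#' @export
write_angle_matrix <- function(series, path) {
  stopifnot(length(series) > 0)
  nf <- vapply(series, `[[`, integer(1), "n_frames")
  if (length(unique(nf)) != 1L) stop("series must have equal frame counts")
  keys <- vapply(series, `[[`, character(1), "key")
  m <- vapply(series, `[[`, numeric(nf[1L]), "angles")
  m <- matrix(m, nrow = nf[1L], dimnames = list(NULL, keys))
  utils::write.table(m, path, sep = "\t", row.names = FALSE, quote = FALSE)
  side <- list(frame_interval = series[[1L]]$frame_interval,
               atom_quadruples = lapply(series, `[[`, "atom_quadruple"))
  names(side$atom_quadruples) <- keys
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_angle_matrix
#' @param frame_interval fallback frame spacing when no sidecar exists.
#' @export
read_angle_matrix <- function(path, frame_interval = 1) {
  m <- utils::read.table(path, header = TRUE, sep = "\t",
                         check.names = FALSE)
  quads <- NULL
  sidecar <- paste0(path, ".json")
  if (file.exists(sidecar)) {
    side <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    frame_interval <- side$frame_interval
    quads <- side$atom_quadruples
  }
  out <- lapply(colnames(m), function(k) {
    quad <- if (!is.null(quads) && k %in% names(quads))
      unlist(quads[[k]]) else rep(NA_character_, 4L)
    dihedral_series(m[[k]], frame_interval, key = k, atom_quadruple = quad)
  })
  names(out) <- colnames(m)
  out
}

#' Write / read transition records as delimited text
#'
#' One row per record: \code{key}, \code{replica}, \code{n}, \code{tau},
#' and the comma-joined transition times.
#'
#' @param records list of [transition_record]s.
#' @param path file path.
#' @return \code{path} (write) / list of records (read), invisibly for write.
#' @export
write_transition_records <- function(records, path) {
  df <- data.frame(
    key = vapply(records, `[[`, character(1), "key"),
    replica = vapply(records, `[[`, integer(1), "replica"),
    n = vapply(records, `[[`, integer(1), "n"),
    tau = vapply(records, `[[`, numeric(1), "tau"),
    times = vapply(records, function(r)
      paste(format(r$times, digits = 15, trim = TRUE, scientific = FALSE),
            collapse = ","), character(1))
  )
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_transition_records
#' @export
read_transition_records <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          colClasses = c("character", "integer", "integer",
                                         "numeric", "character"))
  lapply(seq_len(nrow(df)), function(i) {
    times <- if (nzchar(df$times[i]) && !is.na(df$times[i]))
      as.numeric(strsplit(df$times[i], ",", fixed = TRUE)[[1L]])
    else numeric(0)
    transition_record(times, tau = df$tau[i], key = df$key[i],
                      replica = df$replica[i])
  })
}

#' Write / read a square coupling matrix as delimited text
#'
#' Tab-separated with residue keys as header and first column.  Activity
#' matrices are directional: rows are the affected residue X, columns the
#' influencing residue Y.
#'
#' @param m square numeric matrix with dimnames.
#' @param path file path.
#' @export
write_matrix_txt <- function(m, path) {
  m <- as.matrix(m)
  df <- data.frame(key = rownames(m), m, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_matrix_txt
#' @export
read_matrix_txt <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          check.names = FALSE)
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- df[[1L]]
  m
}

#' Export per-residue scores into the B-factor column of a PDB
#'
#' Writes a copy of the reference structure with each atom's B-factor
#' replaced by its residue's score (dynamical memory, eigenvector component,
#' ...), for sphere-size or colour rendering in molecular viewers.  Residues
#' without a score get 0.
#'
#' @param topology \code{bio3d} \code{pdb} object or PDB path.
#' @param scores named numeric vector, names = residue keys.
#' @param path output PDB path.
#' @export
export_bfactor_pdb <- function(topology, scores, path) {
  pdb <- if (inherits(topology, "pdb")) topology else bio3d::read.pdb(topology)
  atoms <- pdb$atom
  seg <- if (!is.null(atoms$chain) && !all(is.na(atoms$chain))) atoms$chain
         else atoms$segid
  keyv <- .residue_key(seg, atoms$resid, atoms$resno)
  b <- unname(scores[keyv])
  b[is.na(b)] <- 0
  bio3d::write.pdb(pdb, file = path, b = b)
  invisible(path)
}
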