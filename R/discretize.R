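#' State alphabets for dihedral discretization
#'
#' Fixed angular bins partitioning \code{[0, 360)} into discrete rotamer /
#' conformer states.  Protein side-chain chi1 angles get three states:
#' X on \code{[0, 120)}, Y on \code{[120, 240)}, Z on \code{[240, 360)}.
#' DNA glycosidic angles get two: the syn state S on the union
#' \code{[0, 140) U [330, 360)} and the anti state A on \code{[140, 330)}.
#' All bins are half-open so every angle maps to exactly one label.
#' Boundaries are overridable for sensitivity analyses but the defaults are
#' the analysis constants.
#'
#' @param boundaries protein: ascending cut points \code{c(0, b1, b2, 360)};
#'   dna: \code{c(syn_upper, anti_upper)} giving S = [0, syn_upper) U
#'   [anti_upper, 360).
#' @return object of class \code{"state_alphabet"}: list with \code{labels},
#'   \code{assign} (vectorized angle -> label), \code{name}.
#' @examples
#' protein_alphabet()$assign(c(60, 120, 359.9))  # "X" "Y" "Z"
#' dna_alphabet()$assign(c(90, 200, 330))        # "S" "A" "S"
#' @export
protein_alphabet <- function(boundaries = c(0, 120, 240, 360)) {
  stopifnot(length(boundaries) == 4L, boundaries[1L] == 0,
            boundaries[4L] == 360, !is.unsorted(boundaries, strictly = TRUE))
  labels <- c("X", "Y", "Z")
  force(boundaries)
  assign_fun <- function(angle) {
    .check_angle_range(angle)
    labels[findInterval(angle, boundaries, rightmost.closed = FALSE)]
  }
  structure(list(labels = labels, assign = assign_fun, name = "protein",
                 boundaries = boundaries),
            class = "state_alphabet")
}

#' @rdname protein_alphabet
#' @export
dna_alphabet <- function(boundaries = c(140, 330)) {
  stopifnot(length(boundaries) == 2L, boundaries[1L] > 0,
            boundaries[2L] > boundaries[1L], boundaries[2L] < 360)
  labels <- c("S", "A")
  force(boundaries)
  assign_fun <- function(angle) {
    .check_angle_range(angle)
    ifelse(angle < boundaries[1L] | angle >= boundaries[2L], "S", "A")
  }
  structure(list(labels = labels, assign = assign_fun, name = "dna",
                 boundaries = boundaries),
            class = "state_alphabet")
}

.check_angle_range <- function(angle) {
  if (anyNA(angle)) stop("angle must not be NA")
  if (any(angle < 0 | angle >= 360))
    stop("angle must lie in [0, 360); wrap raw dihedrals with wrap_angle()")
  invisible(TRUE)
}

#' Assign a protein chi1 rotamer state
#'
#' @param angle degrees in \code{[0, 360)}.
#' @return label in \code{{"X","Y","Z"}} (protein) or \code{{"S","A"}} (DNA);
#'   vectorized.
#' @export
assign_protein_state <- function(angle) protein_alphabet()$assign(angle)

#' @rdname assign_protein_state
#' @export
assign_dna_state <- function(angle) dna_alphabet()$assign(angle)

#' Per-frame state series
#'
#' @param labels character vector, one state per frame.
#' @param alphabet the [state_alphabet] the labels belong to.
#' @param frame_interval time between frames.
#' @param key residue identifier.
#' @param replica integer replica id.
#' @return object of class \code{"state_series"}.
#' @export
state_series <- function(labels, alphabet, frame_interval = 1,
                         key = NA_character_, replica = 1L) {
  stopifnot(inherits(alphabet, "state_alphabet"))
  if (!all(labels %in% alphabet$labels))
    stop("labels outside the alphabet: ",
         paste(setdiff(unique(labels), alphabet$labels), collapse = ", "))
  if (frame_interval <= 0) stop("frame_interval must be positive")
  structure(list(labels = as.character(labels), alphabet = alphabet,
                 frame_interval = frame_interval, key = as.character(key),
                 replica = as.integer(replica)),
            class = "state_series")
}

#' @export
print.state_series <- function(x, ...) {
  cat(sprintf("<state_series> %s: %d frames, alphabet {%s}, dt = %g\n",
              x$key, length(x$labels), paste(x$alphabet$labels, collapse = ","),
              x$frame_interval))
  invisible(x)
}

#' Discretize a dihedral series into states
#'
#' Maps each frame's angle to its state label.  Frames with an undefined
#' angle (\code{NA}, e.g. from a geometrically degenerate quadruple)
#' propagate the previous frame's label so isolated numerical failures do
#' not create spurious transitions; leading \code{NA}s take the first
#' defined label.
#'
#' @param series a \code{"dihedral_series"} (see [extract_chi1()]) or a bare
#'   numeric vector of angles in \code{[0, 360)}.
#' @param alphabet a [state_alphabet].
#' @param frame_interval,key,replica used when \code{series} is a bare
#'   vector; taken from the series object otherwise.
#' @return a [state_series].
#' @export
discretize_angles <- function(series, alphabet = protein_alphabet(),
                              frame_interval = 1, key = NA_character_,
                              replica = 1L) {
  if (inherits(series, "dihedral_series")) {
    angles <- series$angles
    frame_interval <- series$frame_interval
    key <- series$key
  } else angles <- as.numeric(series)
  ok <- !is.na(angles)
  labs <- rep(NA_character_, length(angles))
  labs[ok] <- alphabet$assign(angles[ok])
  if (!all(ok)) {
    if (!any(ok)) stop("all angles undefined for ", key)
    # carry the previous defined label forward; backfill leading NAs
    idx <- cumsum(ok)
    first <- labs[ok][1L]
    labs <- c(first, labs[ok])[idx + 1L]
  }
  state_series(labs, alphabet, frame_interval, key, replica)
}

#' Detect state transitions
#'
#' A transition is recorded at every frame \code{i >= 1} (0-based) whose
#' label differs from the previous frame's, at time \code{i * frame_interval}
#' (the first frame in the new state).  The observation time is
#' \code{tau = n_frames * frame_interval}.  An optional minimum-dwell filter
#' drops excursions shorter than \code{min_dwell_frames} frames (both the
#' entry and exit transition of the short excursion are removed); it is off
#' by default because it materially changes transition counts.
#'
#' @param series a [state_series] of length >= 2.
#' @param min_dwell_frames drop state visits shorter than this many frames;
#'   \code{1} (default) keeps everything.
#' @return a [transition_record].
#' @export
detect_transitions <- function(series, min_dwell_frames = 1L) {
  stopifnot(inherits(series, "state_series"))
  labs <- series$labels
  n <- length(labs)
  if (n < 2L) stop("need at least two frames")
  if (min_dwell_frames > 1L) {
    r <- rle(labs)
    while (any(short <- r$lengths < min_dwell_frames) && length(r$lengths) > 1L) {
      i <- which(short)[1L]
      # absorb the short visit into its predecessor (or successor if first)
      absorb <- if (i > 1L) i - 1L else i + 1L
      r$values[i] <- r$values[absorb]
      labs2 <- inverse.rle(r)
      r <- rle(labs2)
    }
    labs <- inverse.rle(r)
  }
  chg <- which(labs[-1L] != labs[-n])      # i in 1..n-1, 0-based frame index i
  transition_record(chg * series$frame_interval,
                    tau = n * series$frame_interval,
                    key = series$key, replica = series$replica)
}

#' Keep only well-sampled residues
#'
#' Drops transition records with fewer than \code{min_n} transitions;
#' persistence and exchange statistics are only meaningful when the clock
#' has ticked many times (the default keeps residues with ten or more
#' transitions).  Applied per replica: a residue may be retained in one
#' replica and dropped in another.
#'
#' @param records list of [transition_record]s.
#' @param min_n minimum transition count, \code{>= 1}.
#' @param quiet suppress the message listing dropped residues.
#' @return the retained sublist, with attribute \code{"dropped"} holding the
#'   keys that were removed.
#' @export
filter_min_transitions <- function(records, min_n = 10L, quiet = FALSE) {
  stopifnot(min_n >= 1L)
  if (!length(records)) return(structure(list(), dropped = character(0)))
  ns <- vapply(records, `[[`, integer(1), "n")
  keep <- ns >= min_n
  dropped <- vapply(records[!keep], `[[`, character(1), "key")
  if (length(dropped) && !quiet)
    message(sprintf("dropped %d residue(s) with < %d transitions: %s",
                    length(dropped), min_n,
                    paste(utils::head(dropped, 8L), collapse = ", "),
                    if (length(dropped) > 8L) ", ..." else ""))
  structure(records[keep], dropped = dropped)
}

#' Angular probability density of dihedral angles
#'
#' Histogram-based density over \code{[0, 360)}, integrating to one.  Used
#' as a diagnostic that the state boundaries sit in minima of the pooled
#' angle density.
#'
#' @param angles numeric vector (or list of dihedral series) of angles in
#'   \code{[0, 360)}.
#' @param bin_width degrees; must divide 360.
#' @return data.frame with \code{bin_mid} (degrees) and \code{density}
#'   (per degree); \code{sum(density * bin_width) == 1}.
#' @export
density_profile <- function(angles, bin_width = 5) {
  if (is.list(angles))
    angles <- unlist(lapply(angles, function(s)
      if (inherits(s, "dihedral_series")) s$angles else s))
  if (!length(angles)) stop("no angles supplied")
  if (abs(360 / bin_width - round(360 / bin_width)) > 1e-9)
    stop("bin_width must divide 360")
  .check_angle_range(angles)
  edges <- seq(0, 360, by = bin_width)
  counts <- tabulate(findInterval(angles, edges), nbins = length(edges) - 1L)
  data.frame(bin_mid = edges[-length(edges)] + bin_width / 2,
             density = counts / (sum(counts) * bin_width))
}
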