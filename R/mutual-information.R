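#' Empirical joint state distribution of two residues
#'
#' Plug-in frequencies over simultaneous frames: joint probabilities
#' \eqn{P(X, Y)} and the marginals \eqn{P(X)}, \eqn{P(Y)}.  The joint
#' marginalizes to the marginals exactly by construction.
#'
#' @param x,y [state_series] of equal length from the same replica, or bare
#'   label vectors.
#' @return object of class \code{"joint_distribution"}: list with
#'   \code{joint} (matrix, rows = states of x), \code{px}, \code{py},
#'   \code{n} (sample count).
#' @export
estimate_joint <- function(x, y) {
  lx <- if (inherits(x, "state_series")) x$labels else as.character(x)
  ly <- if (inherits(y, "state_series")) y$labels else as.character(y)
  if (length(lx) != length(ly)) stop("series must have equal length")
  if (!length(lx)) stop("empty series")
  if (inherits(x, "state_series") && inherits(y, "state_series") &&
      !isTRUE(all.equal(x$frame_interval, y$frame_interval)))
    stop("series must share frame_interval")
  tab <- table(factor(lx), factor(ly))
  joint <- tab / sum(tab)
  structure(list(joint = unclass(joint), px = rowSums(joint),
                 py = colSums(joint), n = length(lx)),
            class = "joint_distribution")
}

#' Mutual information between discretized residue states
#'
#' The entropic (thermodynamic) correlation baseline:
#' \deqn{MI(X, Y) = H(X) + H(Y) - H(X, Y)} in nats, with
#' \eqn{H = -\sum p \ln p} and the convention \eqn{0 \ln 0 = 0}.  This is the
#' plug-in estimator on the same state alphabets used for conditional
#' activity (no bias correction).  MI is symmetric and non-negative;
#' independence gives 0, a residue with itself gives its own entropy.
#'
#' @param x a \code{"joint_distribution"} from [estimate_joint()], or a
#'   [state_series] / label vector when \code{y} is supplied.
#' @param y optional second series; when given the joint is estimated first.
#' @return mutual information in nats, \code{>= 0}.
#' @examples
#' a <- rep(c("X", "Y"), 50)
#' mutual_information(a, a)  # ln 2
#' @export
mutual_information <- function(x, y = NULL) {
  joint <- if (inherits(x, "joint_distribution")) x else estimate_joint(x, y)
  p <- joint$joint
  ex <- outer(joint$px, joint$py)
  nz <- p > 0
  mi <- sum(p[nz] * log(p[nz] / ex[nz]))
  max(mi, 0)   # clip the tiny negative round-off of an exactly-independent joint
}

#' Pairwise mutual-information matrix
#'
#' @param series_list list of [state_series] of equal length (same replica).
#' @return symmetric matrix of MI values (nats) with residue-key dimnames;
#'   the diagonal holds each residue's own entropy.
#' @export
mi_matrix <- function(series_list) {
  if (length(series_list) < 2L) stop("need at least two series")
  keys <- vapply(series_list, `[[`, character(1), "key")
  n <- length(series_list)
  M <- matrix(0, n, n, dimnames = list(keys, keys))
  for (i in seq_len(n)) {
    for (j in i:n) {
      M[i, j] <- M[j, i] <- mutual_information(series_list[[i]],
                                               series_list[[j]])
    }
  }
  M
}
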