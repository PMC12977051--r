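#' Circularly shift a transition record
#'
#' Adds an offset to every transition time modulo the observation time and
#' re-sorts.  The shift preserves the residue's single-record waiting-time
#' statistics (up to the one interval cut by the wrap point) while
#' destroying any cross-timing with other residues — the null model for
#' coupling significance.
#'
#' @param record a [transition_record].
#' @param offset time in \code{[0, tau)}.
#' @return the shifted [transition_record].
#' @export
circular_shift <- function(record, offset) {
  stopifnot(inherits(record, "transition_record"))
  if (offset < 0 || offset >= record$tau) stop("offset must lie in [0, tau)")
  if (record$n == 0L || offset == 0) return(record)
  t2 <- (record$times + offset) %% record$tau
  t2[t2 == 0] <- record$tau
  transition_record(sort(t2), tau = record$tau, key = record$key,
                    replica = record$replica)
}

#' Permutation p-value for a directional coupling
#'
#' Empirical one-sided (upper-tail) significance of the observed conditional
#' activity \code{A[X][Y]}: the influencing record Y is circularly shifted
#' by uniformly random offsets, the activity is recomputed against each
#' shifted copy, and
#' \deqn{p = \frac{1 + \#\{A_{null} \ge A_{obs}\}}{n_{perm} + 1}.}
#' The resolution floor is \code{1/(n_permutations + 1)}; with the default
#' 2000 draws, p-values are multiples of about 0.0005.
#'
#' @param x,y [transition_record]s retained by the transition filter.
#' @param n_permutations number of random shifts, \code{>= 1}.
#' @param seed optional integer for reproducible offsets.
#' @return object of class \code{"condact_perm"}: list with
#'   \code{observed_A}, \code{null_samples}, \code{p_value},
#'   \code{n_permutations}, \code{seed}.
#' @export
permutation_pvalue <- function(x, y, n_permutations = 2000L, seed = NULL) {
  stopifnot(inherits(x, "transition_record"), inherits(y, "transition_record"))
  if (n_permutations < 1L) stop("n_permutations must be >= 1")
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
  }
  obs <- conditional_activity(x, y)
  if (is.na(obs)) stop("observed conditional activity is undefined")
  offsets <- stats::runif(n_permutations, 0, y$tau)
  null <- vapply(offsets, function(o)
    conditional_activity(x, circular_shift(y, o)), numeric(1))
  p <- (1 + sum(null >= obs, na.rm = TRUE)) / (n_permutations + 1)
  structure(list(observed_A = obs, null_samples = null, p_value = p,
                 n_permutations = as.integer(n_permutations),
                 seed = if (is.null(seed)) NA_integer_ else as.integer(seed)),
            class = "condact_perm")
}

#' @export
print.condact_perm <- function(x, ...) {
  cat(sprintf("<condact_perm> A = %.4f, p = %.4g (%d circular-shift permutations)\n",
              x$observed_A, x$p_value, x$n_permutations))
  invisible(x)
}

#' Significant inter-residue couplings
#'
#' Long-format table of the strongest directional couplings of a fit with
#' circular-shift permutation p-values: the machine twin of a
#' statistically-significant-couplings table.  Only ordered pairs whose
#' activity reaches \code{min_A} are tested (testing every pair is rarely
#' useful and costs \code{n_permutations} refits each).  Raw p-values are
#' reported by default; Benjamini-Hochberg adjustment is available.
#'
#' @param fit a \code{"condact"} object (single replica).
#' @param records the transition records the fit was computed from.
#' @param min_A test ordered pairs with \code{A >= min_A} (off-diagonal).
#' @param max_pairs cap on the number of pairs tested (strongest first).
#' @param n_permutations,seed passed to [permutation_pvalue()]; the seed is
#'   advanced per pair for independence.
#' @param adjust \code{"none"} (raw p-values) or \code{"BH"}.
#' @return data.frame: \code{residue_X}, \code{residue_Y}, \code{A},
#'   \code{p_value}, ordered by decreasing A.
#' @export
coupling_table <- function(fit, records, min_A = 2, max_pairs = 50L,
                           n_permutations = 2000L, seed = NULL,
                           adjust = c("none", "BH")) {
  stopifnot(inherits(fit, "condact"))
  adjust <- match.arg(adjust)
  A <- fit$activity
  off <- A; diag(off) <- NA
  idx <- which(!is.na(off) & off >= min_A, arr.ind = TRUE)
  if (!nrow(idx))
    return(data.frame(residue_X = character(0), residue_Y = character(0),
                      A = numeric(0), p_value = numeric(0)))
  ord <- order(off[idx], decreasing = TRUE)
  idx <- idx[utils::head(ord, max_pairs), , drop = FALSE]
  keys <- vapply(records, `[[`, character(1), "key")
  p <- numeric(nrow(idx))
  for (k in seq_len(nrow(idx))) {
    rx <- records[[match(rownames(A)[idx[k, 1L]], keys)]]
    ry <- records[[match(colnames(A)[idx[k, 2L]], keys)]]
    p[k] <- permutation_pvalue(rx, ry, n_permutations,
                               seed = if (is.null(seed)) NULL else seed + k)$p_value
  }
  if (adjust == "BH") p <- stats::p.adjust(p, "BH")
  data.frame(residue_X = rownames(A)[idx[, 1L]],
             residue_Y = colnames(A)[idx[, 2L]],
             A = off[idx], p_value = p, row.names = NULL)
}
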