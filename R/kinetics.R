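#' Persistence time of a residue
#'
#' The mean waiting time from a uniformly random observation time until the
#' residue's next state transition,
#' \deqn{\tau_p[X] = \frac{1}{2\tau} \sum_i W(X, T(X,i))^2,}
#' computed over the waiting intervals that partition \code{[0, tau]}: the
#' interval before the first transition, the inter-transition intervals, and
#' the (censored) interval after the last transition.  Because a random time
#' lands in an interval with probability proportional to its length, the
#' length-weighted mean interval divided by two is exactly the random-start
#' average waiting time.
#'
#' @param record a [transition_record] with at least one transition.
#' @return persistence time in the record's time units; \code{NA} for an
#'   empty record (such residues should have been dropped by
#'   [filter_min_transitions()]).
#' @examples
#' persistence_time(transition_record(c(1, 3, 7), tau = 7)) # 1.5
#' @export
persistence_time <- function(record) {
  stopifnot(inherits(record, "transition_record"))
  if (record$n == 0L) return(NA_real_)
  w <- diff(c(0, record$times, record$tau))
  sum(w^2) / (2 * record$tau)
}

#' Exchange time of X following transitions of Y
#'
#' The waiting-interval-weighted average of X's forward recurrence time
#' evaluated at Y's transition times,
#' \deqn{\tau_p[X][Y] = \frac{1}{\tau} \sum_{i=1}^{N(Y)-1}
#'       W(X, T(Y,i+1))\, W(Y, T(Y,i)),}
#' where \eqn{W(Y, T(Y,i)) = T(Y,i+1) - T(Y,i)} is Y's own waiting interval
#' and \eqn{W(X, \cdot)} is X's forward recurrence time ([forward_recurrence]),
#' censored at the trajectory end.  Requires both records to share the same
#' observation time and replica.
#'
#' @param x,y [transition_record]s on the same trajectory; \code{y} needs at
#'   least two transitions.
#' @return exchange time, or \code{NA} when undefined (\code{N(Y) < 2}).
#' @examples
#' r <- transition_record(c(1, 3, 7), tau = 7)
#' exchange_time(r, r) # 8/7
#' @export
exchange_time <- function(x, y) {
  stopifnot(inherits(x, "transition_record"), inherits(y, "transition_record"))
  if (!isTRUE(all.equal(x$tau, y$tau)))
    stop("records must share the same observation time tau")
  if (y$n < 2L) return(NA_real_)
  ty <- y$times
  wy <- diff(ty)                         # W(Y, T(Y,i)), i = 1..N(Y)-1
  wx <- forward_recurrence(x, ty[-1L])   # W(X, T(Y,i+1))
  sum(wx * wy) / x$tau
}

#' Conditional activity A[X][Y]
#'
#' The directional kinetic coupling of residue X to residue Y,
#' \deqn{A[X][Y] = -\ln\!\big(\tau_p[X][Y] / \tau_p[X]\big).}
#' Positive values mean transitions of Y hasten the next transition of X
#' (exchange faster than persistence); zero means kinetic independence;
#' the measure is directional, \eqn{A[X][Y] \ne A[Y][X]} in general.  The
#' diagonal case \code{conditional_activity(x, x)} is the residue's
#' dynamical memory: near zero for memoryless (Poisson) transition
#' statistics, positive when successive waiting times are history-dependent.
#'
#' @param x,y [transition_record]s sharing \code{tau}.
#' @return dimensionless activity in natural-log units; \code{NA} when either
#'   time is undefined or the exchange time is zero (all terms censored).
#' @export
conditional_activity <- function(x, y) {
  tp <- persistence_time(x)
  txy <- exchange_time(x, y)
  if (is.na(tp) || is.na(txy) || tp <= 0 || txy <= 0) return(NA_real_)
  -log(txy / tp)
}

#' Fit the conditional-activity matrix
#'
#' The central estimator: from a list of per-residue transition records
#' (one replica, shared observation time) it computes all pairwise
#' conditional activities \code{A[X][Y]} with rows = affected residue X and
#' columns = influencing residue Y, the per-residue persistence times, and
#' the dynamical memory on the diagonal.
#'
#' @param records list of [transition_record]s with a shared \code{tau} and
#'   replica, typically the output of [detect_transitions()] filtered by
#'   [filter_min_transitions()].  At least two records.
#' @return an object of class \code{"condact"}: list with \code{activity}
#'   (n x n matrix, dimnames = residue keys; \code{NA} where undefined),
#'   \code{persistence} (named vector), \code{memory} (the diagonal),
#'   \code{n_transitions}, \code{tau}, \code{replica}.
#' @seealso [eigendomains()], [pool_replicas()], [coupling_table()],
#'   [memory_report()]
#' @examples
#' r1 <- transition_record(c(1, 3, 7), tau = 7, key = "a")
#' r2 <- transition_record(c(2, 5), tau = 7, key = "b")
#' fit <- condact(list(r1, r2))
#' coef(fit)["a", "a"]  # dynamical memory of residue a: ln(21/16)
#' @export
condact <- function(records) {
  if (!is.list(records) || length(records) < 2L)
    stop("need at least two transition records")
  if (!all(vapply(records, inherits, logical(1), "transition_record")))
    stop("all elements must be transition_record objects")
  taus <- vapply(records, `[[`, numeric(1), "tau")
  if (diff(range(taus)) > 1e-9 * taus[1L])
    stop("all records must share the same observation time tau")
  reps <- vapply(records, `[[`, integer(1), "replica")
  if (length(unique(reps)) != 1L)
    stop("all records must come from the same replica; pool fitted ",
         "objects across replicas with pool_replicas()")
  keys <- vapply(records, `[[`, character(1), "key")
  if (anyDuplicated(keys)) stop("residue keys must be unique")
  n <- length(records)
  tp <- vapply(records, persistence_time, numeric(1))
  A <- matrix(NA_real_, n, n, dimnames = list(keys, keys))
  for (i in seq_len(n)) {
    if (is.na(tp[i]) || tp[i] <= 0) next
    for (j in seq_len(n)) {
      txy <- exchange_time(records[[i]], records[[j]])
      if (!is.na(txy) && txy > 0) A[i, j] <- -log(txy / tp[i])
    }
  }
  names(tp) <- keys
  structure(
    list(activity = A, persistence = tp, memory = diag(A),
         n_transitions = setNames(vapply(records, `[[`, integer(1), "n"), keys),
         tau = taus[1L], replica = reps[1L], sem = NULL, n_replicas = 1L),
    class = "condact"
  )
}

#' @export
print.condact <- function(x, ...) {
  n <- ncol(x$activity)
  cat(sprintf("<condact> conditional-activity matrix: %d residues%s\n", n,
              if (identical(x$replica, "pooled"))
                sprintf(" (pooled over %d replicas)", x$n_replicas)
              else sprintf(", replica %s, tau = %g", x$replica, x$tau)))
  cat("  rows = affected residue X, columns = influencing residue Y\n")
  mem <- sort(x$memory, decreasing = TRUE)
  top <- utils::head(mem[!is.na(mem)], 3L)
  if (length(top))
    cat("  highest dynamical memory:",
        paste(sprintf("%s (%.3f)", names(top), top), collapse = ", "), "\n")
  invisible(x)
}

#' @export
coef.condact <- function(object, ...) object$activity

#' @export
as.matrix.condact <- function(x, ...) x$activity

#' @rdname condact
#' @param object,x a \code{"condact"} fit.
#' @param coupling_threshold off-diagonal activity above which a pair is
#'   reported as coupled in the summary.
#' @param ... unused.
#' @export
summary.condact <- function(object, coupling_threshold = 2, ...) {
  A <- object$activity
  off <- A; diag(off) <- NA
  pairs <- which(!is.na(off) & off >= coupling_threshold, arr.ind = TRUE)
  out <- list(
    n_residues = ncol(A),
    memory = object$memory,
    n_coupled = nrow(pairs),
    top_pairs = if (nrow(pairs)) {
      ord <- order(off[pairs], decreasing = TRUE)
      utils::head(data.frame(
        residue_X = rownames(A)[pairs[ord, 1L]],
        residue_Y = colnames(A)[pairs[ord, 2L]],
        A = off[pairs][ord], row.names = NULL), 10L)
    } else NULL,
    coupling_threshold = coupling_threshold
  )
  class(out) <- "summary.condact"
  out
}

#' @export
print.summary.condact <- function(x, ...) {
  cat(sprintf("Conditional-activity fit over %d residues\n", x$n_residues))
  mem <- x$memory[!is.na(x$memory)]
  cat(sprintf("Dynamical memory (diagonal): median %.3f, max %.3f\n",
              stats::median(mem), max(mem)))
  cat(sprintf("%d ordered pairs with A >= %.2f", x$n_coupled,
              x$coupling_threshold))
  if (!is.null(x$top_pairs)) {
    cat("; strongest:\n")
    print(x$top_pairs, digits = 4)
  } else cat("\n")
  invisible(x)
}

#' @rdname condact
#' @param zlim colour range for the heatmap; defaults to a symmetric range.
#' @export
plot.condact <- function(x, zlim = NULL, ...) {
  A <- x$activity
  A[is.na(A)] <- 0
  if (is.null(zlim)) zlim <- c(-1, 1) * max(abs(A), 1e-12)
  n <- ncol(A)
  # image() draws rows along x; transpose and flip so row X runs top-down
  graphics::image(seq_len(n), seq_len(n), t(A[n:1, , drop = FALSE]),
                  zlim = zlim, xlab = "influencing residue Y",
                  ylab = "affected residue X", axes = FALSE,
                  col = grDevices::hcl.colors(51, "Blue-Red 2"),
                  main = "Conditional activity A[X][Y]", ...)
  graphics::box()
  invisible(x)
}

#' Pool conditional-activity fits across replicas
#'
#' Entrywise mean of the activity matrices over replicas, with the standard
#' error of the mean per entry.  Activities are computed per replica first
#' and averaged afterwards (on the log scale of A); entries defined in no
#' replica stay missing, and the SEM is missing wherever fewer than two
#' replicas define the entry.
#'
#' @param fits list of \code{"condact"} objects over a shared residue
#'   universe (a residue absent from one replica simply contributes a
#'   missing entry there).
#' @return a \code{"condact"} object with \code{replica = "pooled"} and an
#'   additional \code{sem} matrix.
#' @export
pool_replicas <- function(fits) {
  if (!is.list(fits) || !length(fits)) stop("need at least one fit")
  if (!all(vapply(fits, inherits, logical(1), "condact")))
    stop("all elements must be condact fits")
  keys <- unique(unlist(lapply(fits, function(f) rownames(f$activity))))
  n <- length(keys)
  k <- length(fits)
  arr <- array(NA_real_, c(n, n, k), dimnames = list(keys, keys, NULL))
  parr <- matrix(NA_real_, n, k, dimnames = list(keys, NULL))
  for (r in seq_len(k)) {
    ki <- rownames(fits[[r]]$activity)
    arr[ki, ki, r] <- fits[[r]]$activity
    parr[ki, r] <- fits[[r]]$persistence
  }
  mean_na <- function(v) if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)
  sem_na <- function(v) {
    v <- v[!is.na(v)]
    if (length(v) < 2L) NA_real_ else stats::sd(v) / sqrt(length(v))
  }
  A <- apply(arr, c(1, 2), mean_na)
  SEM <- apply(arr, c(1, 2), sem_na)
  structure(
    list(activity = A, persistence = apply(parr, 1, mean_na),
         memory = diag(A), n_transitions = NULL,
         tau = fits[[1L]]$tau, replica = "pooled", sem = SEM,
         n_replicas = k),
    class = "condact"
  )
}

#' Dynamically connected domains from the principal eigenvector
#'
#' Symmetrizes the conditional-activity matrix, \eqn{S = (M + M^T)/2}, and
#' returns the unit-norm eigenvector of its largest eigenvalue.  Residues
#' with the largest components carry the largest modes of correlated
#' kinetic fluctuation and delineate the system's dynamically connected
#' domains.  Missing entries are imputed as 0, the defined independence
#' value.  The global sign is fixed so the largest-magnitude component is
#' positive.
#'
#' @param x a \code{"condact"} fit or a square numeric matrix.
#' @return object of class \code{"condact_domains"}: list with
#'   \code{scores} (named eigenvector components), \code{eigenvalue}
#'   (leading eigenvalue of the symmetrized matrix).  Degenerate (all-zero)
#'   input yields \code{NA} scores.
#' @export
eigendomains <- function(x) {
  M <- if (inherits(x, "condact")) x$activity else as.matrix(x)
  if (nrow(M) != ncol(M)) stop("matrix must be square")
  M[is.na(M)] <- 0
  S <- (M + t(M)) / 2
  keys <- rownames(S)
  if (is.null(keys)) keys <- as.character(seq_len(nrow(S)))
  if (all(S == 0)) {
    return(structure(list(scores = setNames(rep(NA_real_, nrow(S)), keys),
                          eigenvalue = NA_real_),
                     class = "condact_domains"))
  }
  e <- eigen(S, symmetric = TRUE)
  v <- e$vectors[, 1L]
  v <- v / sqrt(sum(v^2))
  if (v[which.max(abs(v))] < 0) v <- -v
  structure(list(scores = setNames(v, keys), eigenvalue = e$values[1L]),
            class = "condact_domains")
}

#' @export
print.condact_domains <- function(x, ...) {
  cat(sprintf("<condact_domains> leading eigenvalue %.4f\n", x$eigenvalue))
  top <- utils::head(sort(abs(x$scores), decreasing = TRUE), 5L)
  cat("  largest components:",
      paste(sprintf("%s (%.3f)", names(top), top), collapse = ", "), "\n")
  invisible(x)
}
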