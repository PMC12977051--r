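#' Transition record: a residue's kinetic clock
#'
#' A transition record holds the sorted times at which one residue's
#' discretized degree of freedom (a side-chain chi1 rotamer state or a DNA
#' glycosidic syn/anti state) changed state, together with the observation
#' time \code{tau} of the trajectory it came from.  All kinetic quantities
#' (persistence time, exchange time, conditional activity) are computed from
#' these records.
#'
#' @param times numeric vector of strictly increasing transition times in
#'   \code{(0, tau]}.  May be empty (a residue that never switched state).
#' @param tau total observation time (trajectory duration), \code{> 0}.
#' @param key residue identifier, e.g. \code{"A:SER:5"}.
#' @param replica integer replica id (replicas are never concatenated; each
#'   gets its own record).
#' @return an object of class \code{"transition_record"}: a list with
#'   elements \code{times}, \code{tau}, \code{key}, \code{replica}, \code{n}.
#' @examples
#' r <- transition_record(c(1, 3, 7), tau = 7)
#' persistence_time(r)
#' @export
transition_record <- function(times, tau, key = NA_character_, replica = 1L) {
  times <- as.numeric(times)
  if (!is.numeric(tau) || length(tau) != 1L || !is.finite(tau) || tau <= 0)
    stop("'tau' must be a single positive number")
  if (anyNA(times) || any(!is.finite(times)))
    stop("transition times must be finite")
  if (length(times) > 1L && any(diff(times) <= 0))
    stop("transition times must be strictly increasing")
  if (length(times) && (times[1L] <= 0 || times[length(times)] > tau))
    stop("transition times must lie in (0, tau]")
  structure(
    list(times = times, tau = tau, key = as.character(key),
         replica = as.integer(replica), n = length(times)),
    class = "transition_record"
  )
}

#' @export
print.transition_record <- function(x, ...) {
  cat(sprintf("<transition_record> %s  replica %d: N = %d transitions, tau = %g\n",
              x$key, x$replica, x$n, x$tau))
  invisible(x)
}

#' Forward recurrence time W(X, t)
#'
#' Time from each query time \code{t} until the record's next transition
#' strictly after \code{t}.  After the last transition the waiting time is
#' censored at the end of the trajectory, \code{W = tau - t}, so that the
#' waiting intervals partition \code{[0, tau]} exactly.
#'
#' @param record a [transition_record].
#' @param t numeric vector of query times in \code{[0, tau]}.
#' @return numeric vector, same length as \code{t}.
#' @export
forward_recurrence <- function(record, t) {
  stopifnot(inherits(record, "transition_record"))
  if (any(t < 0 | t > record$tau)) stop("query times must lie in [0, tau]")
  idx <- findInterval(t, record$times)           # transitions at or before t
  nxt <- c(record$times, Inf)[idx + 1L]
  ifelse(is.finite(nxt), nxt - t, record$tau - t)
}
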