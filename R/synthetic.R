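#' Renewal-process specification
#'
#' Describes a semi-Markov (renewal) state-transition process: successive
#' waiting times are drawn i.i.d. from the chosen distribution and summed
#' until the observation time is exceeded.  Used to generate synthetic
#' transition records with known kinetic structure (Poisson/memoryless with
#' \code{"exponential"}, maximally history-dependent with \code{"fixed"},
#' heavy-tailed with the two-exponential \code{"mixture"}).
#'
#' @param waiting one of \code{"exponential"}, \code{"fixed"},
#'   \code{"mixture"}.
#' @param mean mean waiting time (exponential).
#' @param period clock period (fixed).
#' @param means length-2 means of the mixture components.
#' @param weight probability of the first mixture component.
#' @param tau observation time, \code{> 0}.
#' @return an object of class \code{"renewal_spec"}.
#' @export
renewal_spec <- function(waiting = c("exponential", "fixed", "mixture"),
                         mean = 1, period = 1, means = c(1, 10),
                         weight = 0.5, tau = 100) {
  waiting <- match.arg(waiting)
  if (!is.finite(tau) || tau <= 0) stop("'tau' must be positive")
  mw <- switch(waiting,
    exponential = mean,
    fixed = period,
    mixture = weight * means[1L] + (1 - weight) * means[2L])
  if (!is.finite(mw) || mw <= 0) stop("mean waiting time must be positive")
  if (waiting == "mixture" &&
      (length(means) != 2L || any(means <= 0) || weight < 0 || weight > 1))
    stop("mixture needs two positive means and weight in [0, 1]")
  structure(list(waiting = waiting, mean = mean, period = period,
                 means = means, weight = weight, tau = tau,
                 mean_waiting = mw),
            class = "renewal_spec")
}

.draw_waits <- function(spec, n) {
  switch(spec$waiting,
    exponential = stats::rexp(n, rate = 1 / spec$mean),
    fixed = rep(spec$period, n),
    mixture = {
      pick <- stats::runif(n) < spec$weight
      ifelse(pick, stats::rexp(n, 1 / spec$means[1L]),
             stats::rexp(n, 1 / spec$means[2L]))
    })
}

#' Generate a synthetic renewal transition record
#'
#' @param spec a [renewal_spec].
#' @param key,replica passed to [transition_record()].
#' @param seed optional integer; when given, the RNG state is set locally so
#'   identical spec + seed reproduce the record exactly.
#' @return a [transition_record] with strictly increasing times in
#'   \code{(0, tau]}; possibly empty if the first waiting time exceeds
#'   \code{tau}.
#' @export
generate_renewal <- function(spec, key = "synthetic", replica = 1L,
                             seed = NULL) {
  stopifnot(inherits(spec, "renewal_spec"))
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
  }
  if (spec$waiting == "fixed") {
    times <- seq(spec$period, spec$tau, by = spec$period)
  } else {
    # draw in blocks until the cumulative time passes tau
    block <- max(16L, ceiling(1.5 * spec$tau / spec$mean_waiting))
    times <- numeric(0)
    total <- 0
    while (total <= spec$tau) {
      w <- .draw_waits(spec, block)
      times <- c(times, total + cumsum(w))
      total <- times[length(times)]
    }
    times <- times[times <= spec$tau]
  }
  transition_record(times, tau = spec$tau, key = key, replica = replica)
}

#' Directional coupling specification
#'
#' Ground truth for recovering directional conditional activity: each
#' transition of a master process triggers, with probability
#' \code{trigger_probability}, one response transition in the target at the
#' master time plus a random lag.
#'
#' @param trigger_probability probability in \code{[0, 1]} that a master
#'   transition elicits a response.
#' @param lag \code{"exponential"} or \code{"fixed"} response-lag law.
#' @param lag_mean mean lag (exponential) or the fixed delay; \code{>= 0}.
#' @return object of class \code{"coupling_spec"}.
#' @export
coupling_spec <- function(trigger_probability, lag = c("exponential", "fixed"),
                          lag_mean = NULL) {
  lag <- match.arg(lag)
  if (!is.finite(trigger_probability) || trigger_probability < 0 ||
      trigger_probability > 1)
    stop("'trigger_probability' must be in [0, 1]")
  if (!is.null(lag_mean) && (!is.finite(lag_mean) || lag_mean < 0))
    stop("'lag_mean' must be >= 0")
  structure(list(trigger_probability = trigger_probability, lag = lag,
                 lag_mean = lag_mean),
            class = "coupling_spec")
}

#' Generate a master--slave pair of transition records
#'
#' The master is a plain renewal process.  The target (slave) merges its own
#' baseline renewal transitions with triggered responses: each master
#' transition elicits, with the coupling's trigger probability, one target
#' transition at the master time plus a lag.  The response lag defaults to
#' an exponential with mean 1\% of the master's mean waiting time so
#' exchange times stay well separated from persistence times.  Coincident
#' merged times are perturbed by \code{+tau * 1e-6} to keep the record
#' strictly increasing.
#'
#' @param master a [renewal_spec] for the driving process.
#' @param coupling a [coupling_spec].
#' @param baseline optional [renewal_spec] for the target's own transitions
#'   (must share \code{tau}); \code{NULL} for a purely triggered target.
#' @param keys length-2 character: master and target keys.
#' @param replica,seed as in [generate_renewal()].
#' @return list with elements \code{master} and \code{target}, both
#'   [transition_record]s.
#' @export
generate_coupled_pair <- function(master, coupling, baseline = NULL,
                                  keys = c("master", "target"),
                                  replica = 1L, seed = NULL) {
  stopifnot(inherits(master, "renewal_spec"), inherits(coupling, "coupling_spec"))
  if (!is.null(baseline)) {
    stopifnot(inherits(baseline, "renewal_spec"))
    if (!isTRUE(all.equal(baseline$tau, master$tau)))
      stop("baseline and master must share tau")
  }
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
  }
  tau <- master$tau
  m <- generate_renewal(master, key = keys[1L], replica = replica)
  lag_mean <- if (is.null(coupling$lag_mean)) 0.01 * master$mean_waiting
              else coupling$lag_mean
  triggered <- numeric(0)
  if (m$n > 0L && coupling$trigger_probability > 0) {
    fire <- stats::runif(m$n) < coupling$trigger_probability
    lags <- if (coupling$lag == "fixed") rep(lag_mean, m$n)
            else stats::rexp(m$n, rate = 1 / max(lag_mean, .Machine$double.xmin))
    triggered <- (m$times + lags)[fire]
    triggered <- triggered[triggered <= tau]
  }
  base_times <- if (is.null(baseline)) numeric(0)
                else generate_renewal(baseline)$times
  all_t <- sort(c(base_times, triggered))
  eps <- tau * 1e-6
  if (length(all_t) > 1L) {
    for (i in 2:length(all_t))
      if (all_t[i] <= all_t[i - 1L]) all_t[i] <- all_t[i - 1L] + eps
    all_t <- all_t[all_t <= tau]
  }
  list(master = m,
       target = transition_record(all_t, tau = tau, key = keys[2L],
                                  replica = replica))
}

#' Angle-emission specification
#'
#' Turns a transition record plus a state sequence into a noisy per-frame
#' dihedral series: in each inter-transition interval the angle is drawn as
#' a Gaussian around the active state's center, then wrapped into
#' \code{[0, 360)}.  Emulates the peaked per-state dihedral densities of
#' real side chains.  Centers must sit far enough inside their state's
#' angular bin that at least 99\% of emissions stay in the bin.
#'
#' @param state_centers named numeric vector, degrees in \code{[0, 360)},
#'   names = state labels of \code{alphabet}.
#' @param angular_noise_sd Gaussian noise, degrees.
#' @param frame_interval frame spacing, same time units as the record.
#' @param alphabet a [state_alphabet] (defaults to the 3-state protein
#'   alphabet) used to validate the centers.
#' @return object of class \code{"angle_emission_spec"}.
#' @export
angle_emission_spec <- function(state_centers = c(X = 60, Y = 180, Z = 300),
                                angular_noise_sd = 8, frame_interval = 1,
                                alphabet = protein_alphabet()) {
  if (angular_noise_sd < 0 || frame_interval <= 0)
    stop("noise sd must be >= 0 and frame_interval > 0")
  if (is.null(names(state_centers)) ||
      !all(names(state_centers) %in% alphabet$labels))
    stop("state_centers must be named by labels of the alphabet")
  # >= 99% of emissions must fall inside the center's own bin
  z <- stats::qnorm(0.995)
  for (lab in names(state_centers)) {
    ctr <- state_centers[[lab]]
    if (alphabet$assign(ctr) != lab)
      stop(sprintf("center %g lies outside the bin of state %s", ctr, lab))
    edges <- (ctr + c(-1, 1) * z * angular_noise_sd) %% 360
    if (any(alphabet$assign(edges) != lab))
      stop(sprintf(
        "noise sd %g too large: <99%% of emissions for state %s stay in its bin",
        angular_noise_sd, lab))
  }
  structure(list(state_centers = state_centers,
                 angular_noise_sd = angular_noise_sd,
                 frame_interval = frame_interval, alphabet = alphabet),
            class = "angle_emission_spec")
}

#' Emit a noisy dihedral-angle series from a transition record
#'
#' Frames are placed at times \code{0, dt, 2dt, ...} up to the record's
#' observation time; the state active at each frame is the one holding in
#' the inter-transition interval containing that frame, per the supplied
#' state sequence (one label per interval, i.e. \code{N + 1} labels for
#' \code{N} transitions).  Discretizing the output and re-detecting
#' transitions recovers the input record to within one frame interval.
#'
#' @param record a [transition_record].
#' @param emission an [angle_emission_spec].
#' @param state_sequence character vector of length \code{record$n + 1};
#'   consecutive labels should differ or the corresponding transition
#'   disappears on re-discretization.
#' @param seed optional integer for reproducible noise.
#' @return a \code{"dihedral_series"} (see [extract_chi1()]) with angles in
#'   \code{[0, 360)}.
#' @export
emit_angle_series <- function(record, emission, state_sequence, seed = NULL) {
  stopifnot(inherits(record, "transition_record"),
            inherits(emission, "angle_emission_spec"))
  if (length(state_sequence) != record$n + 1L)
    stop("state_sequence needs one label per inter-transition interval ",
         sprintf("(%d, got %d)", record$n + 1L, length(state_sequence)))
  if (!all(state_sequence %in% names(emission$state_centers)))
    stop("state_sequence contains labels without an emission center")
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
  }
  dt <- emission$frame_interval
  n_frames <- floor(record$tau / dt + 1e-9) + 1L   # frames at 0, dt, ..., tau
  t_frames <- (seq_len(n_frames) - 1L) * dt
  interval <- findInterval(t_frames, record$times) + 1L
  labs <- state_sequence[interval]
  centers <- emission$state_centers[labs]
  ang <- (centers + stats::rnorm(n_frames, 0, emission$angular_noise_sd)) %% 360
  dihedral_series(angles = as.numeric(ang), frame_interval = dt,
                  key = record$key,
                  atom_quadruple = rep("synthetic", 4L))
}
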