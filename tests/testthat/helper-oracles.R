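# Independent oracles used across the suite.  These deliberately do not call
# the package's own computational path.

# dihedral of four 3D points, signed degrees in (-180, 180], standard
# atan2 formulation
ref_dihedral <- function(p1, p2, p3, p4) {
  cross <- function(a, b) c(a[2] * b[3] - a[3] * b[2],
                            a[3] * b[1] - a[1] * b[3],
                            a[1] * b[2] - a[2] * b[1])
  b0 <- p1 - p2
  b1 <- (p3 - p2) / sqrt(sum((p3 - p2)^2))
  b2 <- p4 - p3
  v <- b0 - sum(b0 * b1) * b1
  w <- b2 - sum(b2 * b1) * b1
  atan2(sum(cross(b1, v) * w), sum(v * w)) * 180 / pi
}

# Monte-Carlo persistence time: average forward recurrence time from
# uniformly random start times, computed by direct search (no findInterval)
mc_persistence <- function(times, tau, n = 1e5, seed = 1) {
  set.seed(seed)
  t0 <- runif(n, 0, tau)
  w <- vapply(t0, function(ti) {
    nxt <- times[times > ti]
    if (length(nxt)) nxt[1] - ti else tau - ti
  }, numeric(1))
  mean(w)
}

# entropy in nats with 0 ln 0 = 0
ref_entropy <- function(p) {
  p <- p[p > 0]
  -sum(p * log(p))
}

# MI via the KL form on an explicit joint matrix
ref_mi <- function(joint) {
  px <- rowSums(joint); py <- colSums(joint)
  s <- 0
  for (i in seq_along(px)) for (j in seq_along(py))
    if (joint[i, j] > 0) s <- s + joint[i, j] * log(joint[i, j] / (px[i] * py[j]))
  s
}

# wrap a joint matrix into the package's joint_distribution container
as_joint <- function(m) {
  structure(list(joint = m, px = rowSums(m), py = colSums(m), n = NA_integer_),
            class = "joint_distribution")
}
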