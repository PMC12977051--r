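# the worked 3-transition example: transitions at 1, 3, 7 with tau = 7
toy <- transition_record(c(1, 3, 7), tau = 7, key = "toy")

test_that("persistence time matches the hand computation and the random-start definition", {
  expect_equal(persistence_time(toy), 1.5)
  # Monte-Carlo oracle: average forward recurrence from uniform start times
  expect_equal(mc_persistence(toy$times, 7, n = 1e5, seed = 2), 1.5,
               tolerance = 0.01)
  expect_true(is.na(persistence_time(transition_record(numeric(0), tau = 5))))
})

test_that("waiting intervals partition [0, tau] exactly", {
  for (s in 1:10) {
    r <- generate_renewal(renewal_spec("exponential", mean = 2, tau = 100),
                          seed = s)
    expect_equal(sum(diff(c(0, r$times, r$tau))), r$tau)
  }
})

test_that("self-exchange of the toy record includes the censored final term", {
  expect_equal(exchange_time(toy, toy), 8 / 7)
  # N(Y) = 2: a single-term sum
  y2 <- transition_record(c(2, 5), tau = 7, key = "y2")
  # W(toy, 5) = 7 - 5 = 2, W(y2 at 2) = 3
  expect_equal(exchange_time(toy, y2), 2 * 3 / 7)
  expect_true(is.na(exchange_time(toy, transition_record(3, tau = 7))))
  expect_error(exchange_time(toy, transition_record(1, tau = 9)), "tau")
})

test_that("conditional activity of the toy record on itself is ln(21/16)", {
  expect_equal(conditional_activity(toy, toy), log(21 / 16))
})

test_that("periodic clock: tp = c/2 exactly and memory converges to -ln 2", {
  clk <- generate_renewal(renewal_spec("fixed", period = 2, tau = 1e4))
  expect_equal(persistence_time(clk), 1)
  # end censoring contributes O(1/N); the criterion band is +/- 0.01
  expect_lt(abs(conditional_activity(clk, clk) + log(2)), 0.01)
  expect_lt(abs(conditional_activity(clk, clk) + log(2)), 3 / clk$n)
  expect_equal(mc_persistence(clk$times, 1e4, n = 2e4, seed = 3),
               persistence_time(clk), tolerance = 0.02)
})

test_that("exponential renewal: tp approaches the mean waiting time", {
  tps <- vapply(1:60, function(s)
    persistence_time(generate_renewal(
      renewal_spec("exponential", mean = 3, tau = 3000), seed = s)),
    numeric(1))
  # <W^2> / (2 <W>) = m for the exponential law
  expect_lt(abs(mean(tps) - 3), 3 * sd(tps) / sqrt(length(tps)))
})

test_that("independent renewals give near-zero activity in both directions", {
  As <- t(vapply(1:40, function(s) {
    x <- generate_renewal(renewal_spec("exponential", mean = 1, tau = 2000),
                          seed = 2 * s, key = "x")
    y <- generate_renewal(renewal_spec("exponential", mean = 1.5, tau = 2000),
                          seed = 2 * s + 1, key = "y")
    c(conditional_activity(x, y), conditional_activity(y, x))
  }, numeric(2)))
  for (j in 1:2)
    expect_lt(abs(mean(As[, j])), 3 * sd(As[, j]) / sqrt(nrow(As)))
})

test_that("activity matrix is oriented rows = affected X, columns = influencing Y", {
  ms <- generate_coupled_pair(
    renewal_spec("exponential", mean = 10, tau = 5000),
    coupling_spec(1, "fixed", 0.01),
    baseline = renewal_spec("exponential", mean = 100, tau = 5000),
    keys = c("m", "s"), seed = 21)
  fit <- condact(list(ms$master, ms$target))
  A <- coef(fit)
  expect_gt(A["s", "m"], 1)                  # master drives slave
  expect_gt(A["s", "m"], A["m", "s"] + 1)    # and not the reverse
  expect_equal(fit$memory, diag(A))
  expect_equal(conditional_activity(ms$target, ms$master), A["s", "m"])
})

test_that("non-commutativity is real but symmetrization removes it exactly", {
  set.seed(5)
  recs <- lapply(1:4, function(i)
    generate_renewal(renewal_spec("exponential", mean = i, tau = 500),
                     key = paste0("r", i), seed = 30 + i))
  A <- coef(condact(recs))
  expect_false(isTRUE(all.equal(A, t(A))))
  S <- (A + t(A)) / 2
  expect_equal(S - t(S), matrix(0, 4, 4, dimnames = dimnames(A)))
})

test_that("pooling averages entrywise with SEM and respects missingness", {
  mk <- function(vals, keys = c("a", "b")) {
    f <- list(activity = matrix(vals, 2, 2, dimnames = list(keys, keys)),
              persistence = setNames(c(1, 1), keys), tau = 10,
              replica = 1L, sem = NULL, n_replicas = 1L)
    f$memory <- diag(f$activity)
    class(f) <- "condact"
    f
  }
  p <- pool_replicas(list(mk(rep(1, 4)), mk(rep(3, 4))))
  expect_equal(unname(p$activity), matrix(2, 2, 2))
  expect_equal(unname(p$sem), matrix(1, 2, 2))
  expect_identical(p$replica, "pooled")
  # single replica: mean is that replica, SEM missing
  p1 <- pool_replicas(list(mk(rep(2, 4))))
  expect_equal(unname(p1$activity), matrix(2, 2, 2))
  expect_true(all(is.na(p1$sem)))
  # an entry missing in one of three replicas: mean over the two defined
  m3 <- mk(rep(4, 4)); m3$activity[1, 2] <- NA
  p3 <- pool_replicas(list(mk(rep(1, 4)), mk(rep(3, 4)), m3))
  expect_equal(p3$activity[1, 2], 2)
  expect_equal(p3$activity[1, 1], 8 / 3)
})

test_that("eigendomains match closed forms and a dense eigensolver oracle", {
  d2 <- eigendomains(matrix(c(0, 1, 1, 0), 2, 2))
  expect_equal(d2$eigenvalue, 1)
  expect_equal(unname(d2$scores), rep(1 / sqrt(2), 2))
  # 6x6 two-block matrix, stronger first block
  B <- matrix(0, 6, 6)
  B[1:3, 1:3] <- 2; B[4:6, 4:6] <- 0.5; diag(B) <- 0
  B[1, 4] <- 0.1   # slight asymmetry to exercise symmetrization
  dom <- eigendomains(B)
  S <- (B + t(B)) / 2
  e <- eigen(S, symmetric = TRUE)         # dense oracle
  expect_equal(dom$eigenvalue, e$values[1])
  v <- e$vectors[, 1]; v <- v * sign(v[which.max(abs(v))])
  expect_equal(unname(dom$scores), v, tolerance = 1e-12)
  expect_gt(sum(dom$scores[1:3]^2), 0.9)  # mass on the stronger block
  expect_equal(sum(dom$scores^2), 1)
  # symmetric input: symmetrization is the identity
  expect_equal(eigendomains(S)$scores, dom$scores)
  # degenerate all-zero matrix
  expect_true(is.na(eigendomains(matrix(0, 3, 3))$eigenvalue))
})

test_that("condact validates its inputs", {
  expect_error(condact(list(toy)), "at least two")
  expect_error(condact(list(toy, transition_record(1:3, tau = 9, key = "z"))),
               "tau")
  expect_error(condact(list(toy, toy)), "unique")
  r2 <- transition_record(c(2, 5), tau = 7, key = "toy2", replica = 2L)
  expect_error(condact(list(toy, r2)), "replica")
})
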