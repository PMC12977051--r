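test_that("fixed-period renewal is a deterministic clock", {
  r <- generate_renewal(renewal_spec("fixed", period = 1, tau = 10))
  expect_equal(r$times, as.numeric(1:10))
  expect_equal(r$n, 10L)
})

test_that("exponential renewal counts follow Poisson statistics", {
  r <- generate_renewal(renewal_spec("exponential", mean = 1, tau = 1e4),
                        seed = 11)
  expect_lt(abs(r$n - 1e4), 3 * sqrt(1e4))
  # mean count over many seeds approaches tau / mean
  counts <- vapply(1:100, function(s)
    generate_renewal(renewal_spec("exponential", mean = 5, tau = 500),
                     seed = s)$n, numeric(1))
  expect_lt(abs(mean(counts) - 100), 3 * sd(counts) / sqrt(100))
})

test_that("degenerate and invalid renewal specs behave as documented", {
  # waiting time likely exceeding tau: an empty record is legitimate
  r <- generate_renewal(renewal_spec("exponential", mean = 1e6, tau = 10),
                        seed = 1)
  expect_s3_class(r, "transition_record")
  expect_true(r$n == 0L || all(r$times > 0 & r$times <= 10))
  expect_error(renewal_spec("exponential", mean = -1), "positive")
  expect_error(renewal_spec("fixed", period = 0), "positive")
  expect_error(renewal_spec(tau = 0), "positive")
})

test_that("generation is reproducible under a fixed seed and strictly increasing", {
  spec <- renewal_spec("mixture", means = c(1, 10), weight = 0.3, tau = 200)
  a <- generate_renewal(spec, seed = 5)
  b <- generate_renewal(spec, seed = 5)
  expect_identical(a$times, b$times)
  for (s in 1:20) {
    r <- generate_renewal(spec, seed = s)
    expect_true(all(diff(r$times) > 0))
    expect_true(all(r$times > 0 & r$times <= spec$tau))
  }
})

test_that("coupled pair: trigger 0 and empty master give baseline-only targets", {
  m <- renewal_spec("exponential", mean = 5, tau = 100)
  base <- renewal_spec("exponential", mean = 2, tau = 100)
  p0 <- generate_coupled_pair(m, coupling_spec(0), baseline = base, seed = 3)
  expect_gt(p0$target$n, 0)
  # no baseline and trigger 0: nothing can fire
  p00 <- generate_coupled_pair(m, coupling_spec(0), seed = 3)
  expect_equal(p00$target$n, 0L)
  # empty master with trigger 1: target is baseline only
  empty_master <- renewal_spec("exponential", mean = 1e7, tau = 100)
  p1 <- generate_coupled_pair(empty_master, coupling_spec(1, "fixed", 0.01),
                              baseline = base, seed = 4)
  expect_equal(p1$master$n, 0L)
  expect_gt(p1$target$n, 0)
})

test_that("full trigger with tiny lag places one response per master transition", {
  m <- renewal_spec("exponential", mean = 10, tau = 1000)
  p <- generate_coupled_pair(m, coupling_spec(1, "fixed", 0.01), seed = 8)
  in_range <- p$master$times + 0.01 <= 1000
  expect_equal(p$target$n, sum(in_range))
  expect_equal(p$target$times[seq_len(sum(in_range))],
               (p$master$times + 0.01)[in_range], tolerance = 1e-9)
  expect_true(all(diff(p$target$times) > 0))
})

test_that("coupling_spec validates its inputs", {
  expect_error(coupling_spec(1.5), "\\[0, 1\\]")
  expect_error(coupling_spec(0.5, "fixed", lag_mean = -1), ">= 0")
})

test_that("angle emission round-trips through discretization at zero noise", {
  r <- transition_record(c(10, 25, 40), tau = 50, key = "rt")
  em <- angle_emission_spec(angular_noise_sd = 0, frame_interval = 1)
  s <- emit_angle_series(r, em, c("X", "Y", "Z", "X"))
  rec <- detect_transitions(discretize_angles(s, protein_alphabet()))
  expect_equal(rec$times, r$times)   # transitions at integer times, dt = 1
  # recovered state sequence matches the input
  ss <- discretize_angles(s, protein_alphabet())
  expect_equal(rle(ss$labels)$values, c("X", "Y", "Z", "X"))
})

test_that("noisy emission recovers the transition count for almost all seeds", {
  set.seed(99)
  # transitions well separated relative to the frame interval so every one
  # is resolvable
  r <- transition_record(cumsum(runif(20, 3, 8)), tau = 200, key = "rt")
  labs <- rep(c("X", "Y", "Z"), length.out = 21)
  em <- angle_emission_spec(state_centers = c(X = 60, Y = 180, Z = 300),
                            angular_noise_sd = 8, frame_interval = 1)
  hits <- vapply(1:100, function(s) {
    ser <- emit_angle_series(r, em, labs, seed = s)
    detect_transitions(discretize_angles(ser, protein_alphabet()))$n == r$n
  }, logical(1))
  expect_gte(mean(hits), 0.99)
})

test_that("single-state sequences and invalid emission specs are caught", {
  r <- transition_record(numeric(0), tau = 20, key = "flat")
  em <- angle_emission_spec(angular_noise_sd = 0)
  s <- emit_angle_series(r, em, "Y")
  expect_equal(detect_transitions(discretize_angles(s, protein_alphabet()))$n,
               0L)
  expect_error(angle_emission_spec(state_centers = c(X = 150)), "outside")
  expect_error(angle_emission_spec(angular_noise_sd = 40), "99")
  expect_error(emit_angle_series(r, em, c("X", "Y")), "one label per")
})
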