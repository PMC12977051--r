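test_that("residue positions are quadruple centers of geometry in nm", {
  p <- withr::local_tempfile(fileext = ".pdb")
  lines <- c(
    sprintf("ATOM  %5d %-4s %-3s %1s%4d    %8.3f%8.3f%8.3f  1.00  0.00",
            1:4, c(" N", " CA", " CB", " OG"), "SER", "A", 1,
            c(0, 0, 0, 2), c(0, 0, 2, 2), c(0, 2, 2, 2)),
    "END")
  writeLines(lines, p)
  ser <- list("A:SER:1" = dihedral_series(90, key = "A:SER:1",
                                          atom_quadruple = c("N", "CA", "CB", "OG")))
  pos <- residue_positions(p, series = ser)
  # Angstrom coordinates (0,0,0),(0,0,2),(0,2,2),(2,2,2): center (0.5,1,1.5) A
  expect_equal(unname(pos["A:SER:1", ]), c(0.05, 0.10, 0.15))
})

test_that("CA positions are selectable and averaged over frames", {
  p <- withr::local_tempfile(fileext = ".pdb")
  write_fixture_pdb(p, chi_angles = list(SER = c(60, 300)))
  pos <- residue_positions(p, point = "CA")
  expect_equal(unname(pos["A:SER:3", ]), c(2, 0, 0))  # CA at x = 20 A
})

# a 3-residue toy: mutual distances 1 nm, one pair coupled in both directions
toy_matrix <- function(vals = c(ab = 3, ba = 2.5)) {
  M <- matrix(0, 3, 3, dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  M["a", "b"] <- vals[["ab"]]
  M["b", "a"] <- vals[["ba"]]
  M
}
toy_positions <- function() {
  # equilateral triangle of side 1.2 nm: all pair distances fall safely
  # inside the [1.0, 1.5) bin, away from bin edges
  P <- 1.2 * rbind(a = c(0, 0, 0), b = c(1, 0, 0), c = c(0.5, sqrt(3) / 2, 0))
  colnames(P) <- c("x", "y", "z")
  P
}

test_that("fraction_correlated counts ordered pairs per distance bin", {
  fr <- fraction_correlated(toy_matrix(), toy_positions(), threshold = 2,
                            bin_width = 0.5, max_dist = 2)
  # 6 ordered pairs all at 1 nm: 2 of 6 reach the threshold
  bin <- fr[fr$bin_mid_nm == 1.25, ]
  expect_equal(bin$n_pairs, 6)
  expect_equal(bin$fraction, 2 / 6)
  # diagonal (distance 0) bin: no memory >= 2
  expect_equal(fr$fraction[1], 0)
  # bins with no pairs are missing, not zero
  expect_true(is.na(fr$fraction[fr$bin_mid_nm == 0.25]))
  # threshold above the maximum: all occupied bins drop to 0
  fr0 <- fraction_correlated(toy_matrix(), toy_positions(), threshold = 10,
                             bin_width = 0.5, max_dist = 2)
  expect_equal(fr0$fraction[fr0$bin_mid_nm == 1.25], 0)
  # everything above threshold: fraction 1
  M1 <- toy_matrix(); M1[] <- 5
  fr1 <- fraction_correlated(M1, toy_positions(), threshold = 2,
                             bin_width = 0.5, max_dist = 2)
  expect_equal(fr1$fraction[fr1$bin_mid_nm == 1.25], 1)
  expect_equal(fr1$fraction[1], 1)
})

test_that("raising the threshold never raises a bin fraction and pairs are conserved", {
  set.seed(14)
  n <- 12
  keys <- sprintf("r%02d", 1:n)
  M <- matrix(rexp(n * n), n, n, dimnames = list(keys, keys))
  P <- matrix(runif(n * 3, 0, 4), n, 3, dimnames = list(keys, NULL))
  prev <- fraction_correlated(M, P, threshold = 0, bin_width = 0.5,
                              max_dist = 8)
  expect_equal(sum(prev$n_pairs[-1]), n * (n - 1))   # ordered off-diagonal pairs
  for (thr in c(0.5, 1, 2, 4)) {
    cur <- fraction_correlated(M, P, threshold = thr, bin_width = 0.5,
                               max_dist = 8)
    ok <- !is.na(cur$fraction)
    expect_true(all(cur$fraction[ok] <= prev$fraction[ok] + 1e-12))
    prev <- cur
  }
  # unordered counting halves the pair count
  sym <- fraction_correlated(M, P, threshold = 0, bin_width = 0.5,
                             max_dist = 8, symmetric = TRUE)
  expect_equal(sum(sym$n_pairs[-1]), n * (n - 1) / 2)
})

test_that("distance-decaying coupling yields a decaying profile", {
  set.seed(25)
  n <- 20
  keys <- sprintf("r%02d", 1:n)
  P <- matrix(runif(n * 3, 0, 5), n, 3, dimnames = list(keys, NULL))
  D <- as.matrix(dist(P))
  # coupling strength decays with separation plus noise
  M <- 4 * exp(-D / 1.5) + matrix(rnorm(n * n, 0, 0.1), n, n)
  dimnames(M) <- list(keys, keys)
  fr <- fraction_correlated(M, P, threshold = 1, bin_width = 1, max_dist = 8)
  ok <- !is.na(fr$fraction) & fr$n_pairs > 3
  expect_lt(cor(seq_along(fr$fraction)[ok], fr$fraction[ok],
                method = "spearman"), 0)
})

test_that("distance_profile pools replicas with SEM and applies the MI rule", {
  P <- toy_positions()
  m1 <- toy_matrix(c(ab = 3, ba = 2.5))
  m2 <- toy_matrix(c(ab = 3, ba = 1))   # second replica: only one direction
  mi <- matrix(0.05, 3, 3, dimnames = dimnames(m1))
  mi["a", "b"] <- mi["b", "a"] <- 0.5
  diag(mi) <- 1
  prof <- distance_profile(list(m1, m2), P, mi_matrices = list(mi, mi),
                           ca_threshold = 2, bin_width = 0.5, max_dist = 2)
  row <- prof[prof$bin_mid_nm == 1.25, ]
  expect_equal(row$fraction_CA, mean(c(2 / 6, 1 / 6)))
  expect_equal(row$sem_CA, sd(c(2 / 6, 1 / 6)) / sqrt(2))
  # MI threshold = 0.2 * max offdiag (0.5) = 0.1: only the a-b unordered pair
  expect_equal(row$fraction_MI, 1 / 3)
  expect_equal(attr(prof, "pair_counting")[["MI"]], "unordered")
})
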