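# Programmatic PDB fixtures: a 5-residue peptide (ALA-GLY-SER-VAL-LYS) and a
# 2-nucleotide DNA strand (DG, DT), written as (multi-model) PDB text.
# Torsion-bearing atoms are placed on a construction whose dihedral equals a
# requested angle: with b1 projecting onto +y in the plane perpendicular to
# the central bond (x-axis), placing the fourth atom at azimuth -theta gives
# torsion +theta (verified against ref_dihedral in the tests).

.pdb_atom_line <- function(serial, name, resname, chain, resno, xyz) {
  name4 <- if (nchar(name) < 4) paste0(" ", name) else name
  sprintf("ATOM  %5d %-4s %-3s %1s%4d    %8.3f%8.3f%8.3f  1.00  0.00",
          serial, name4, resname, chain, resno, xyz[1], xyz[2], xyz[3])
}

# atoms of one torsion unit at x-offset `off`, with chi = theta degrees;
# returns named list of coordinates for N-like, CA-like, CB-like, G-like atoms
.torsion_unit <- function(off, theta) {
  phi <- theta * pi / 180
  list(a1 = c(off - 0.5, 1.4, 0),                        # N  / O4'
       a2 = c(off, 0, 0),                                # CA / C1'
       a3 = c(off + 1.5, 0, 0),                          # CB / N9|N1
       a4 = c(off + 2.0, 1.2 * cos(phi), 1.2 * sin(phi)))# G  / C4|C2
}

# chi_angles: named list, e.g. list(SER = c(60, 300), VAL = 100, LYS = 250,
# DG = 90, DT = 200); each vector is one angle per model (recycled to the
# max length).  drop_atom: optionally omit one atom name from one residue.
write_fixture_pdb <- function(path, chi_angles = list(SER = 60, VAL = 100,
                                                      LYS = 250, DG = 90,
                                                      DT = 200),
                              drop_atom = NULL) {
  n_models <- max(vapply(chi_angles, length, integer(1)))
  chi <- lapply(chi_angles, rep_len, n_models)
  residues <- list(
    list(resname = "ALA", chain = "A", resno = 1, off = 0,
         atoms = c("N", "CA", "CB")),
    list(resname = "GLY", chain = "A", resno = 2, off = 10,
         atoms = c("N", "CA")),
    list(resname = "SER", chain = "A", resno = 3, off = 20,
         atoms = c("N", "CA", "CB", "OG")),
    list(resname = "VAL", chain = "A", resno = 4, off = 30,
         atoms = c("N", "CA", "CB", "CG1")),
    list(resname = "LYS", chain = "A", resno = 5, off = 40,
         atoms = c("N", "CA", "CB", "CG")),
    list(resname = "DG", chain = "B", resno = 1, off = 50,
         atoms = c("O4'", "C1'", "N9", "C4")),
    list(resname = "DT", chain = "B", resno = 2, off = 60,
         atoms = c("O4'", "C1'", "N1", "C2"))
  )
  lines <- character(0)
  for (m in seq_len(n_models)) {
    if (n_models > 1) lines <- c(lines, sprintf("MODEL     %4d", m))
    serial <- 0L
    for (res in residues) {
      theta <- if (res$resname %in% names(chi)) chi[[res$resname]][m] else 0
      u <- .torsion_unit(res$off, theta)
      coords <- list(u$a1, u$a2, u$a3, u$a4)[seq_along(res$atoms)]
      for (k in seq_along(res$atoms)) {
        if (!is.null(drop_atom) && res$resname == drop_atom$resname &&
            res$atoms[k] == drop_atom$name) next
        serial <- serial + 1L
        lines <- c(lines, .pdb_atom_line(serial, res$atoms[k], res$resname,
                                         res$chain, res$resno, coords[[k]]))
      }
    }
    if (n_models > 1) lines <- c(lines, "ENDMDL")
  }
  writeLines(c(lines, "END"), path)
  invisible(path)
}

# synthetic angle-series collection with a planted structure: one
# high-memory residue (periodic clock), one master-slave coupled pair, and
# independent Poisson residues; returns the list of dihedral_series plus the
# planted keys
make_planted_system <- function(tau = 4000, dt = 1, seed = 7,
                                n_background = 3) {
  set.seed(seed)
  em <- angle_emission_spec(angular_noise_sd = 6, frame_interval = dt)
  rand_states <- function(n) {
    # state sequence with consecutive labels distinct
    labs <- character(n)
    labs[1] <- sample(c("X", "Y", "Z"), 1)
    if (n > 1) for (i in 2:n)
      labs[i] <- sample(setdiff(c("X", "Y", "Z"), labs[i - 1]), 1)
    labs
  }
  series <- list()
  # planted high-memory residue: bursty two-timescale renewal (waiting-time
  # CV >> 1 makes successive waits history-dependent in the random-start
  # sense, i.e. strongly positive A[X][X])
  bursty <- generate_renewal(
    renewal_spec("mixture", means = c(2, 200), weight = 0.9, tau = tau),
    key = "memory")
  series$memory <- emit_angle_series(bursty, em, rand_states(bursty$n + 1))
  # planted directional pair; the lag is a few frame intervals so the
  # response stays resolvable after discretization
  pair <- generate_coupled_pair(
    renewal_spec("exponential", mean = 25, tau = tau),
    coupling_spec(1, "fixed", lag_mean = 2.5 * dt),
    baseline = renewal_spec("exponential", mean = 400, tau = tau),
    keys = c("master", "slave"))
  series$master <- emit_angle_series(pair$master, em,
                                     rand_states(pair$master$n + 1))
  series$slave <- emit_angle_series(pair$target, em,
                                    rand_states(pair$target$n + 1))
  # independent background residues
  for (b in seq_len(n_background)) {
    r <- generate_renewal(renewal_spec("exponential", mean = 30, tau = tau),
                          key = sprintf("bg%d", b))
    series[[r$key]] <- emit_angle_series(r, em, rand_states(r$n + 1))
  }
  list(series = series, planted_memory = "memory",
       planted_pair = c(slave = "slave", master = "master"))
}
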