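# condact

Kinetic correlation analysis of molecular-dynamics trajectories through
**conditional activity** — a directional, time-resolved coupling measure
between residues of proteins and nucleic acids.

## Who this is for

Researchers in structural bioinformatics and molecular modelling who have MD
trajectories of a protein, DNA, or protein–DNA system (e.g. a nucleosome
core particle) and want to map allosteric communication that is invisible to
structural/entropic correlation: which residues have history-dependent
("high-memory") side-chain dynamics, which residue drives which, which
domains are kinetically connected, and over what spatial range kinetic
coupling persists compared with mutual information.

## The method

Each residue contributes one dihedral degree of freedom — side-chain χ₁
(N–CA–CB–γ) for amino acids, the glycosidic torsion (O4′–C1′–N9–C4 for
purines, O4′–C1′–N1–C2 for pyrimidines) for DNA.  Angles are wrapped onto
[0°, 360°) and discretized with fixed bins: protein states X/Y/Z on
120°-wide bins, DNA syn/anti states S = [0°,140°) ∪ [330°,360°), A =
[140°,330°).  The times at which a residue changes state form its kinetic
clock; residues with fewer than ten transitions are dropped.

From the clocks of residues X and Y over observation time τ:

* persistence time τₚ[X] = (1/2τ) Σᵢ W(X, T(X,i))² — the mean wait from a
  random time until X's next transition (W is the forward recurrence time);
* exchange time τₚ[X][Y] = (1/τ) Σᵢ W(X, T(Y,i+1))·W(Y, T(Y,i)) — the same
  average evaluated at Y's transitions;
* conditional activity **A[X][Y] = −ln(τₚ[X][Y] / τₚ[X])** — zero under
  independence, positive when transitions of Y hasten transitions of X,
  directional (A[X][Y] ≠ A[Y][X]).  The diagonal A[X][X] is the residue's
  dynamical memory (0 for Poisson statistics, −ln 2 for a perfect clock,
  large and positive for bursty multi-timescale dynamics).

Downstream: the principal eigenvector of the symmetrized matrix scores
dynamically connected domains; circular-shift permutations give empirical
p-values for the strongest couplings; a distance profile compares the
fraction of kinetically coupled pairs (A ≥ 2) with the mutual-information
fraction as separation grows.  See the vignette
(`vignettes/conditional-activity.Rmd`) for conventions (censoring, replica
pooling, matrix orientation) and the simulator design.

## Worked example

Synthetic ground truth: one bursty high-memory residue (`mem`), a
master→slave driven pair, and a memoryless bystander (`bg`):

```r
library(condact)
set.seed(1)
tau <- 3000
mem <- generate_renewal(renewal_spec("mixture", means = c(2, 200),
                                     weight = 0.9, tau = tau), key = "mem")
pair <- generate_coupled_pair(
  renewal_spec("exponential", mean = 25, tau = tau),
  coupling_spec(1, "fixed", lag_mean = 0.5),
  baseline = renewal_spec("exponential", mean = 400, tau = tau),
  keys = c("master", "slave"))
bg <- generate_renewal(renewal_spec("exponential", mean = 30, tau = tau),
                       key = "bg")
fit <- condact(list(mem, pair$master, pair$target, bg))
round(coef(fit), 3)
#>           mem master  slave     bg
#> mem     4.073 -0.029 -0.027 -0.023
#> master  0.329  0.120  0.123  0.022
#> slave   0.422  3.992  0.121 -0.003
#> bg     -0.107 -0.046 -0.024 -0.291
```

Rows are the affected residue, columns the influencing residue.  The
diagonal recovers the planted memory structure: `mem` (4.07, strongly
history-dependent) versus ≈0 for the Poisson residues.  The off-diagonal
`A["slave","master"] = 3.99` recovers the planted direction of influence,
with no back-coupling (`A["master","slave"] = 0.12`).

```r
permutation_pvalue(pair$target, pair$master, n_permutations = 999, seed = 2)
#> <condact_perm> A = 3.9923, p = 0.001 (999 circular-shift permutations)
eigendomains(fit)
#> <condact_domains> leading eigenvalue 4.1056
#>   largest components: mem (0.992), slave (0.093), master (0.086), bg (0.015)
```

The coupling is significant at the permutation resolution floor, and the
eigenvector concentrates on the residues carrying the kinetic signal.

For trajectory input, `extract_chi1()` / `extract_glycosidic()` produce the
angle series from a PDB topology plus DCD or multi-model-PDB coordinates,
and `run_condact(condact_config(...))` executes the whole pipeline
(discretize → filter → activity → MI → significance → spatial profile →
report) with a JSON manifest.  The same stages are available from a shell
via `Rscript inst/scripts/condact <subcommand>`.

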