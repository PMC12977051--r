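---
title: "Conditional activity: kinetic correlation analysis of dihedral transitions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Conditional activity: kinetic correlation analysis of dihedral transitions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(condact)
```

## The problem and the model

Residues in proteins and nucleic acids communicate not only through
structural (entropic) correlation but through the *timing* of their
conformational dynamics: a side chain may flip rotamer states in response to
another residue's flip without any change in either residue's state
populations.  Classical mutual information is blind to such purely kinetic
coupling.  This package quantifies it through **conditional activity**, a
directional, time-resolved correlation measure built from the transition
times of discretized dihedral angles.

Each residue contributes one degree of freedom: the first side-chain torsion
chi1 (N–CA–CB–gamma) for amino acids, and the glycosidic base–sugar torsion
(O4'–C1'–N9–C4 for purines, O4'–C1'–N1–C2 for pyrimidines) for DNA, which
distinguishes the syn and anti base orientations.  Angles are wrapped onto
[0°, 360°) — negative torsions are replaced by their secondary angle — and
discretized with fixed half-open bins placed in the minima of the pooled
angle density: three protein states (X on [0, 120), Y on [120, 240), Z on
[240, 360)) and two DNA states (syn S on [0, 140) ∪ [330, 360), anti A on
[140, 330)).  The frames at which a residue's state changes are its
*transition times* \(T(X, i)\); the sorted list is the residue's kinetic
clock, observed over the trajectory duration \(\tau\).

Three quantities follow from the clocks.  The **persistence time**

\[
\tau_p[X] \;=\; \frac{1}{2\tau} \sum_i W(X, T(X,i))^2
\]

is the mean waiting time from a uniformly random observation time until X's
next transition, where \(W(X,t)\) is the forward recurrence time (time from
\(t\) to the next transition of X).  Because a random time lands in a
waiting interval with probability proportional to the interval's length, the
length-weighted mean of the intervals divided by two equals that
random-start average exactly.  The **exchange time**

\[
\tau_p[X][Y] \;=\; \frac{1}{\tau} \sum_{i=1}^{N(Y)-1}
  W(X, T(Y, i+1))\; W(Y, T(Y, i))
\]

is the analogous average of X's forward recurrence time, evaluated at Y's
transition times and weighted by Y's waiting intervals.  Their log-ratio is
the **conditional activity**

\[
A[X][Y] \;=\; -\ln\!\frac{\tau_p[X][Y]}{\tau_p[X]},
\]

which is zero when X's dynamics are independent of Y, positive when a
transition of Y hastens the next transition of X, and directional:
\(A[X][Y] \ne A[Y][X]\) in general.  The diagonal \(A[X][X]\) is the
residue's **dynamical memory**: zero for memoryless (Poisson) transition
statistics, positive when successive waiting times are history-dependent
(bursty, multi-timescale dynamics), and negative for clock-like regularity —
a strictly periodic process has \(A[X][X] = -\ln 2\), because the random-start
wait is half a period while the post-transition wait is a full one.

Two downstream views summarize the matrix.  The principal eigenvector of the
symmetrized matrix \(S = (M + M^\top)/2\) scores each residue's
participation in the largest mode of correlated kinetic fluctuation; sets of
residues with large components form *dynamically connected domains*.  And
binning residue pairs by spatial separation gives the fraction of coupled
pairs as a function of distance, compared against the same fraction computed
from mutual information, \(MI = H(X) + H(Y) - H(X,Y)\) in nats on the same
state alphabets.

## Conventions and numerical choices

Several small choices are forced by finite trajectories; the package makes
them explicitly and consistently:

* **Boundary censoring.** The waiting intervals used for \(\tau_p[X]\) are
  the full partition of \([0, \tau]\): the stretch before the first
  transition, the inter-transition intervals, and the stretch after the last
  transition.  The forward recurrence time after the last transition is
  censored at the trajectory end, \(W = \tau - t\).  This keeps
  \(\sum W = \tau\) exactly (so the \(1/2\tau\) prefactor yields exactly the
  random-start average) and keeps every quantity finite.  The effect is
  \(O(1/N)\) and immaterial for residues passing the transition filter.
* **Transition filter.** Only residues with at least ten transitions (per
  replica) enter the analysis; persistence and exchange statistics need
  \(N \gg 1\).  The filter is applied per replica: a residue may be retained
  in one replica and dropped in another.
* **Transition time convention.** A transition is stamped at the first frame
  in the new state (\(i \times \Delta t\), 0-based).  Any consistent
  convention shifts all clocks equally and changes waiting times by at most
  one frame.
* **Replicas.** Series are never concatenated across replicas (the seam
  would fabricate a transition).  Activities are computed per replica on the
  log scale and then averaged entrywise; the standard error of the mean over
  replicas accompanies every pooled entry.
* **Undefined frames.** A geometrically degenerate torsion (collinear atoms)
  yields an undefined angle for that frame; the previous frame's state label
  is carried forward so an isolated numerical failure cannot fabricate two
  transitions.
* **Missing entries.** Residue pairs with undefined exchange times stay
  missing rather than infinite; for the eigenvector computation missing
  entries are imputed as 0, the defined independence value.
* **Matrix orientation.** Rows are the affected residue X, columns the
  influencing residue Y; every output file states this, because transposed
  conventions are the easiest way to corrupt a directional analysis.
* **Logs.** Natural logarithm throughout; MI is reported in nats.  The MI
  estimator is the plug-in (maximum-likelihood) estimator with
  \(0 \ln 0 = 0\) and no bias correction.
* **Dwell filter.** An optional minimum-dwell filter (drop state visits
  shorter than k frames) exists but is off by default: it materially changes
  transition counts and must be a conscious choice.

## Significance of couplings

For the strongest directional couplings the package attaches an empirical
one-sided p-value from a **circular-shift null**: the influencing residue's
clock is shifted by a uniformly random offset modulo \(\tau\) (preserving its
waiting-time statistics while destroying all cross-timing) and the activity
is recomputed; \(p = (1 + \#\{A_{\mathrm{null}} \ge A_{\mathrm{obs}}\}) /
(n_{\mathrm{perm}} + 1)\).  The default of 2000 shifts puts the resolution
floor at about 0.0005.  This null is a reconstruction — it is the
minimal-assumption permutation scheme for point processes — and raw
p-values are reported by default, with Benjamini–Hochberg adjustment behind
a flag.  Only pairs whose activity reaches the coupling threshold are
tested; each test costs a full refit per permutation.

## The synthetic generator, and what passing tests mean

Because the estimator's defining behaviours are distributional, the package
ships a first-class simulator rather than stored fixtures:

* **Renewal records** with exponential (memoryless), fixed-period
  (clock-like) or two-exponential-mixture (bursty, high waiting-time CV)
  waiting laws.  These have known limits: exponential gives
  \(\tau_p \to\) the mean and \(A[X][X] \to 0\); a clock gives
  \(\tau_p = c/2\) and \(A[X][X] \to -\ln 2\); a 90/10 mixture of 2- and
  200-unit waits gives strongly positive memory.
* **Master–slave pairs**: each master transition triggers, with a chosen
  probability, one response transition at the master time plus a lag
  (default: exponential with mean 1% of the master's mean wait, keeping
  exchange times well separated from persistence times).  Ground truth for
  the directional recovery \(A[\mathrm{slave}][\mathrm{master}] \gg
  A[\mathrm{master}][\mathrm{slave}]\).
* **Angle emission**: per-frame Gaussian angles around per-state centers
  (default 60°/180°/300°, noise 8°), validated so at least 99% of emissions
  stay inside their state's bin — the round-trip through discretization
  recovers the planted clock to within one frame.

The simulator emulates the *statistics* the estimator consumes — renewal
clocks, directional triggering, peaked angle densities — not physical
dynamics: there are no forces, no correlated backbone motion, no
autocorrelated noise within a state, and transitions are instantaneous.
Passing tests therefore demonstrate that the estimator recovers known
kinetic structure from data of this form; they do not validate force fields
or sampling adequacy of any particular MD system.  For real trajectories the
transition filter and the replica SEM are the guards against
under-sampling.

Test and example problem sizes (observation times of \(10^3\)–\(10^4\) time
units, 5–10 residues, 100-seed null batteries, 199–2000 permutations) were
chosen as the smallest sizes at which the distributional checks have clear
resolution — e.g. the \(3\,\mathrm{SE}\) Poisson-null band at
\(N \approx 10^4\) transitions resolves memory of ±0.03.

## Tunable parameters

| parameter | default | units | role |
|---|---|---|---|
| protein state bins | 0/120/240/360 | degrees | chi1 rotamer states X, Y, Z |
| DNA state bins | 140, 330 | degrees | syn S = [0,140)∪[330,360), anti A |
| `min_transitions` | 10 | count/replica | retention filter |
| `coupling_threshold` | 2 | nat-log units | "correlated" cutoff, ≈20% of a typical top inter-residue activity |
| `memory_threshold` | 4 | nat-log units | high-memory reporting cutoff |
| `mi_threshold_frac` | 0.2 | fraction of max off-diagonal MI | mirrors the activity rule for the MI curve |
| `bin_width_nm`, `max_dist_nm` | 0.5, 10 | nm | distance profile bins |
| `n_permutations` | 2000 | count | p-value resolution ≈ 0.0005 |

Residue reference positions for the distance profile default to the center
of geometry of the dihedral quadruple's atoms on the time-averaged
structure (Cα or C1' selectable); coordinates from PDB input are converted
from Å to nm.

## Design decisions that were genuinely open

* The 3-state/2-state alphabets are fixed constants, not learned from the
  density; the density profile is provided as a diagnostic that the
  boundaries sit in density minima, and the boundaries are overridable in
  the configuration.
* Replica pooling averages activities *after* the log transform (per-replica
  A, then entrywise mean), which is what makes the per-bin SEM over
  replicas well defined.
* The MI threshold for the distance profile uses the same fractional rule as
  conditional activity (20% of the off-diagonal maximum), since MI lives on
  a different scale and a shared absolute cutoff would be meaningless.
* The distance-0 bin of the profile is the diagonal of the matrix (each
  residue against itself) at the same threshold as the off-diagonal bins.
* Trajectory input is read through `bio3d`: PDB topologies with DCD or
  multi-model-PDB coordinates.  Other MD formats should be converted
  upstream, or per-residue angle series can be supplied directly as
  delimited text (one column per residue, JSON sidecar for the frame
  interval) — the precomputed-series path treats the package purely as the
  statistics engine.

## Worked example

```{r example}
set.seed(1)
tau <- 3000
# a bursty high-memory residue, a driven pair, and a memoryless bystander
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
summary(fit)
eigendomains(fit)
permutation_pvalue(pair$target, pair$master, n_permutations = 999, seed = 2)
```

The diagonal shows the planted memory structure (strongly positive for the
bursty residue, near zero for the Poisson ones), the off-diagonal
`A["slave", "master"]` recovers the planted direction of influence, and the
circular-shift p-value sits at its resolution floor.

## Known limitations

* The plug-in MI estimator is biased upward at short series; since it is
  used as a thresholded comparison curve rather than an estimand, no
  correction is applied.
* Exchange times need at least two transitions of the influencing residue
  and a positive sum; heavily censored pairs come back missing rather than
  extreme, which is the conservative behaviour.
* p-values from circular shifts assume approximate stationarity of the
  clocks over the trajectory; drifting systems (e.g. an unfolding event)
  violate the null in both directions.
* The distance profile uses one reference geometry per replica; it does not
  track time-resolved distances.
* Only chi1 and the glycosidic torsion are extracted; chi2+, backbone and
  sugar-pucker angles are out of scope.
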