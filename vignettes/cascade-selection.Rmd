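---
title: "Adaptive cascade selection of ligand-binding pathways: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Adaptive cascade selection of ligand-binding pathways}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pacsmd)
```

## The problem and the method

Ligand binding is a rare event: a free ligand finds its buried binding site on
a timescale far beyond what a single brute-force trajectory can cover.
`pacsmd` implements the parallel-cascade-selection family of adaptive
sampling protocols. The idea is a ratchet built from many cheap, short
simulations:

1. Run N independent short stochastic-dynamics segments, each recording M
   snapshots.
2. Score every one of the N x M snapshots by a reaction coordinate (RC) that
   measures progress toward binding — by default d_COM, the distance between
   the centre of mass of a ligand copy and that of the binding-site
   selection.
3. Rank the pool ascending in the RC and select the best N snapshots.
4. Restart N new segments from the selected snapshots, with velocities drawn
   fresh from the Maxwell–Boltzmann distribution at the run temperature.
5. Repeat until the best RC of a cycle falls below a cutoff, the RC
   distribution stops changing, or a cycle limit is reached.

Fresh velocity draws at every restart are essential: they are the stochastic
perturbation that lets descendants of one snapshot explore different
continuations. The targeted variant ranks by RMSD to a known product
structure instead of d_COM; both, plus a distance-matrix difference score, a
radius of gyration, and weighted composites of any of these, are available
as `rc_spec()` kinds.

The protocol samples *pathways*, not an equilibrium ensemble: selection
deliberately biases where segments start. Free energies are therefore
estimated afterwards with a Markov state model (MSM) built on the sampled
frames (below), and even then the result from cascade-biased data should be
read as a survey of the binding funnel, not an exact equilibrium profile.
On unbiased equilibrium data the same pipeline converges to the Boltzmann
answer, which is what the package's tests assert.

## The built-in model system

The loop is engine-agnostic; the package drives any backend implementing the
two-function adapter contract (`propagate`, `regenerate_velocities`). The
built-in substrate is a reduced Langevin model chosen so every stage runs on
one CPU in seconds:

- a frozen binding site at `site_center` carrying an attractive Gaussian
  funnel well of depth `well_depth` (units of kBT) and width `well_width`;
- a soft-core sphere of radius `excluded_radius` standing in for the protein
  body (harmonic wall, stiffness `wall_stiffness`);
- a harmonic outer confinement beyond `confinement_radius` (stiffness
  `confinement_stiffness`) bounding the search volume, playing the role of a
  simulation box;
- n single-particle ligand copies with a compact-support pairwise repulsion
  (`copy_repulsion_strength`, `copy_repulsion_range`) so a multi-copy ligand
  environment raises the effective concentration without aggregating. A
  hexagonal six-site rigid copy (`ring_copy_coords()`) is provided to
  exercise the extended-ligand coordinates (COM, radius of gyration,
  distance-matrix scores).

Units are reduced: kBT = 1, mass = 1, lengths on a roughly angstrom-like
scale. Dynamics is BAOAB-split Langevin integration, which samples the
configurational Boltzmann distribution with small time-step bias and is the
standard splitting for this purpose. The integrator consumes R's RNG, so a
`set.seed()`-derived stream makes every segment bit-for-bit reproducible;
stream seeds are derived by a stable hash of (run seed, purpose, cycle,
replica), so results are independent of execution order and of whether a run
was checkpointed and resumed.

Reactants are built by `arrange_ligand_copies()`: copies are placed uniformly
at random in a spherical shell around the site with a minimum pairwise
separation, by rejection sampling with an explicit attempt budget — an
infeasible packing fails loudly naming the violated constraint rather than
looping forever.

### Velocity regeneration at restarts

Stored snapshot velocities are never reused: every selected seed gets a fresh
Maxwell–Boltzmann draw at segment start. Reusing velocities would make the N
descendants of a twice-selected snapshot identical; regeneration is both the
method's perturbation mechanism and what makes the snapshot archive (which
stores positions only) sufficient for exact resume.

## Reaction coordinates and multi-copy scoring

A snapshot holds several ligand copies but the engine ranks whole snapshots,
so a reduction rule is needed. The default scores a snapshot by the
*minimum* d_COM over its copies: any one copy binding terminates the search,
so the best copy is what matters. The alternative — ranking every
(snapshot, copy) pair separately — is available via
`rc_spec(copy_reduction = "per_copy")`; with single-particle copies the two
orderings coincide on the best copy, and the min-reduction is the default
because it keeps one score per restartable object.

COM weights default to unit weights over the selected (carbon-like) atoms;
mass weighting is available through the selection's `weights`. Composite
scores need a units-reconciliation rule before weighting; components are
z-scored over the snapshot pool being ranked (`normalize = "zscore"`), which
makes weights dimensionless and pool-relative. A raw weighted sum
(`normalize = "none"`) is available when components share units. The
superposition RMSD uses the Kabsch algorithm restricted to proper rotations,
so a mirror image does not count as a match.

Tie-breaks in ranking are deterministic — (cycle, replica, frame) order —
and when fewer distinct snapshots than N exist, seeds are recycled
round-robin in rank order. Both choices favour reproducibility over
arbitrariness.

## Termination, convergence and aggregation

Three exits, tested in order after every cycle:

- **cutoff** — the best RC of the cycle fell below `cutoff`. Practically the
  cutoff is set from a known bound structure (e.g. the ligand-site COM
  distance measured in a reference complex) when one exists.
- **converged** — the L1 distance between RC histograms averaged over the
  last `convergence_window` cycles and over the preceding window fell below
  `convergence_tol`. Bins are fixed (20 bins spanning zero to the first
  cycle's maximum RC) so successive windows are comparable. Defaults: window
  5 cycles, tolerance 0.05. This is the fallback when no reference complex
  provides a cutoff.
- **max_cycles** — the hard limit.

Copies can drift into aggregates, which wastes the multi-copy concentration
advantage. `detect_aggregation()` single-links copies whose COM distance is
below `aggregation_threshold`; with `aggregation_policy = "reset"`, selected
seeds with aggregated copies have every copy except the best re-randomised
into the arrangement shell before propagation. Keeping the best copy
guarantees the reset never discards sampling progress.

## The Markov-state-model post-analysis

`msm_profile()` (and `profile_along_rc()` on a finished run) converts RC
trajectories into a free-energy profile:

1. **Microstates** — k-means on the RC values (k-means++ seeding, Lloyd
   iterations, fixed seed; default k = 30).
2. **Lag selection** — implied timescales t_i = −τ / ln λ_i(τ) from the
   transition-matrix eigenvalues; the smallest lag in the grid whose slowest
   timescale changes by less than `plateau_tol` (relative, default 0.1)
   versus the next grid point is taken. Plateauing timescales are the usual
   evidence that the discretised dynamics is approximately Markovian at that
   lag. Default grid: 1, 2, 5, 10 frames.
3. **Estimation** — transition counts use a sliding window within each
   (cycle, replica) segment only; segments are independent restarts, so
   counting across them would fabricate transitions. The reversible
   estimator is the closed-form symmetrised-count formula
   T_ij = (c_ij + c_ji) / Σ_j (c_ij + c_ji), which satisfies detailed
   balance exactly (π ∝ row sums of C + Cᵀ) and is deterministic; an
   iterative reversible maximum-likelihood fit is deliberately out of scope.
   Estimation is restricted to the largest connected state set, with a
   warning naming how many states were dropped.
4. **Profile** — stationary distribution from the eigenvector of eigenvalue
   one, then F_i = −kBT ln(π_i / max_k π_k), pinning F = 0 at the most
   populated microstate.

Numerical conventions: row-stochasticity is enforced to 1e-10 in tests;
complex or non-positive eigenvalues yield undefined (`NA`) timescales rather
than fabricated ones; eigenvalues within 1e-12 of one yield `Inf`;
zero-probability states get `F = Inf`. A one-state model skips lag selection
(there is no relaxation to converge).

## Fixtures: what they emulate and what they do not

The four named fixtures in `make_fixture()` are the package's desk-scale
study conditions. Defaults follow the protocol's standard setup where one
exists — N = 10 segments per cycle, M = 10 snapshots per segment, six ligand
copies arranged so they do not initially interact — and otherwise were
chosen once as physically sensible values and frozen.

- **funnel-easy** (demonstrations, smoke tests): depth 6 kBT, confinement
  radius 6, friction 5, cutoff 1.8. Plain dynamics binds on its own.
- **funnel-hard** (the enrichment benchmark): depth 8 kBT, confinement
  radius 15, friction 40, copies starting 10–13 from the site, cutoff 2.0,
  50-cycle budget. The fixture's defining contract is a separation of
  sampling regimes: the mean first-passage time of a freely diffusing copy
  to the cutoff sphere (~10^4 reduced time units at D = kBT/γ = 0.025)
  exceeds the total simulated time of one run budget (~3 x 10^3 copy-time
  units across 10 replicas x 6 copies), so brute-force dynamics rarely
  binds, while per-cycle selection of the best of 600 snapshots advances the
  record RC by a few tenths of a length unit per cycle and closes the ~8
  unit gap comfortably within the budget. The enrichment study in the test
  suite and acceptance script measures exactly this contrast over 20 seeded
  trials per arm, together with the 6-copy versus 1-copy comparison.
- **double-well-1d** (Boltzmann oracle for the MSM): U(x) = h(x²−1)² +
  (ΔU/2)·tanh(x/0.2), defaults h = 2, ΔU = 2 kBT. The smooth step keeps the
  two wells mirror-shaped to ~1%, so the analytic basin split (computed by
  quadrature, `double_well_delta_F()` ≈ 1.94 kBT) is essentially ΔU. The
  barrier parameter is set so the slowest interbasin relaxation (tens of
  time units) is far shorter than the default sampling length (hundreds of
  time units per walker), making the fixture usable as an oracle at test
  budgets; walkers start from the basin Boltzmann split and discard a
  burn-in, so no initialisation bias survives.
- **markov-2state**: discrete segments from stated flip probabilities; the
  closed-form oracle for counting, estimation, timescales (t₂ = −τ/ln(1 −
  p01 − p10)) and stationary distributions.

Problem sizes in the test suite and acceptance script — 20 trials per arm of
the enrichment study, 10^5 frames for equilibrium statistics, 2.4 x 10^5
frames for the double-well profile — were chosen as the smallest sizes at
which the asserted tolerances are comfortably resolved.

What passing these tests shows: the selection loop, bookkeeping, estimators
and profile machinery are correct on a substrate whose ground truth is
known. What they cannot show: force-field accuracy, solvent and
electrostatic effects, conformational gating of real binding sites, or the
quality of any particular all-atom setup — the toy substrate has no internal
protein degrees of freedom at all. Those questions belong to the external
engine driven through the adapter contract.

## Known limitations

- Free-energy profiles from cascade-selected data inherit the selection
  bias; no reweighting (e.g. multi-ensemble estimators) is attempted, and
  kinetics (rates, mean first-passage times) are deliberately not reported —
  restart perturbation breaks the time-series interpretation.
- The reversible estimator is the symmetrised-count closed form, not the
  iterative maximum-likelihood fit; for heavily non-equilibrium count
  matrices the two differ.
- Resume is supported for per-cycle ranking only; global-pool ranking
  (`rank_scope = "global"`) would need the full cross-cycle pool
  reconstructed at restore time.
- Single-particle copies are points: orientational degrees of freedom of
  real ligands are only exercised through the optional ring geometry in the
  coordinate functions, not in the dynamics.
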