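---
title: "Weighted-ensemble path sampling in wepath: model, estimators, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Weighted-ensemble path sampling in wepath}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wepath)
```

## The weighted-ensemble algorithm

A WE simulation maintains `M` trajectories ("walkers"), each carrying a
statistical weight, and alternates two steps.  (1) *Propagation*: every
walker advances for a fixed interval τ under unmodified stochastic
dynamics.  (2) *Resampling*: walkers are binned on a progress coordinate;
in each occupied bin, high-weight walkers are split (children share the
parent's phase-space point and divide its weight evenly) and the two
lowest-weight walkers are merged repeatedly (one survivor, drawn with
probability proportional to weight, carries the summed weight) until the
bin holds its target count.  Splitting changes no expectation value;
merging preserves every weighted observable in expectation.  Total weight
is therefore conserved exactly and the ensemble's dynamics remain
unbiased — the central invariant, tested to 1e-12 over hundreds of
iterations.

Two operating modes are provided.  In *equilibrium* mode nothing else
happens, and state definitions can be chosen after the run; this is the
package default.  In *recycling* (steady-state) mode, walkers entering a
target state are restarted from fresh initial-state draws with unchanged
weight, producing a nonequilibrium steady state whose arrival flux is the
inverse mean first passage time (the Hill relation).

Rate constants use the history-labeled decomposition: each walker carries
a label `U` or `B` recording whether it was more recently in the unbound
or the bound state (the encounter intermediate and unassigned regions
never relabel).  The "binding" steady state consists of label-`U` weight;
conditional fluxes count the weight of label-`U` walkers entering a state
per iteration, divided by τ.  State entries are detected at τ resolution
only, so sub-τ recrossings are invisible — a deliberate limitation shared
with the analysis convention the estimators assume.  Each arrival counts
exactly once per crossing.

## The toy association model

The synthetic system is a patchy-sphere pair: a fixed receptor (radius
`R_rec`, patch axis +z) and a mobile ligand (radius `R_lig`, orientation a
unit quaternion, two anchor points on the patch axis) inside a reflecting
shell of radius `R_out`.  The interaction

U = U_rep(r) − ε f(r) [ g(cos θ_r)^p_rec · g(cos θ_l)^p_lig + w_enc · g(cos θ_r)² (1 − cos² θ_l) ]

with g(x) = max(x, 0), a C¹ radial switch f (1 at contact, 0 at `r_cut`)
and a soft quadratic core U_rep, creates exactly the three-basin topology
the kinetics assume:

* an **unbound** region (separation ≥ 20, where U = 0 exactly because
  `r_cut` = 30 < contact + 20);
* an **encounter** basin — ligand at the receptor patch but misoriented —
  of depth `w_enc · ε` = 4 kT (the second term is maximal at cos θ_r = 1,
  cos θ_l = 0 and vanishes at full alignment);
* a **bound** basin of depth ε = 10 kT at aligned contact, where the
  anchor-point binding RMSD is 0.

Defaults (reduced units, kT = 1, lengths Å-like, times ps-like):
`R_rec = 12`, `R_lig = 8` (contact 20), `ε = 10`, `p_rec = p_lig = 4`,
`w_enc = 0.4`, `D_t = 0.5`, `D_r = 0.02`, `dt = 0.05`, `R_out = 48`,
`r_cut = 30`, `k_rep = 100`.  The geometry is chosen so that the *printed
state thresholds of the study conditions* (unbound ≥ 20; encounter RMSD in
[4, 20] with separation ≤ 3; bound RMSD ≤ 3.5 with separation ≤ 3)
delineate the basins correctly: with anchors at the ligand poles
(0, 0, ±8), a far-side contact gives RMSD ≈ 43 (not an encounter), a
side-on contact ≈ 25–30, and a patch-side misoriented contact ≈ 11 —
inside the encounter window.  The diffusion constants give a binding MFPT
of ~4 × 10³ time units from the initial ensemble, large enough that
binding is a rare event per τ yet affordable for brute-force validation.

Propagation is Euler–Maruyama overdamped Langevin: translational drift
−(D_t/kT)∇U·dt plus Gaussian noise of variance 2 D_t dt, reflecting at
`R_out`; rotational diffusion of variance 2 D_r dt about random axes with
torque drift −a × ∂U/∂a.  A step larger than `R_rec` aborts with advice
to reduce `dt` (never observed at the defaults; the `toy_params()`
validator also rejects dt/stiffness combinations that could).  All
randomness flows from a counter-based splitmix64 stream keyed by
(seed, walker id, iteration): trajectories are bitwise reproducible, call
order never matters, and split children (which receive fresh ids)
decorrelate immediately.

What the generator emulates: diffusive association with orientational
gating, a metastable on-pathway intermediate, a two-dimensional progress
coordinate with the same functional form (minimum separation; binding RMSD
of anchor points after receptor superposition), and realistic
rare-event statistics for the estimators.  What it does not: atomistic
force fields, explicit solvent, conformational flexibility, electrostatic
steering, or desolvation effects.  Passing tests therefore validate the
*sampling and estimation machinery*, not any biophysical prediction about
a real protein pair.

## Bin schemes and progress coordinate

* `preparatory_scheme()` — 1-D RMSD scheme: 0.1-unit cells on [0, 3),
  0.5-unit cells on [3, 10), one open-ended cell: 45 cells.
* `binding_scheme(stage)` — separation split at 5 (in contact / not in
  contact; the boundary value 5 itself is "not in contact"), with the
  contact side subdivided in binding RMSD: 0.5-unit cells on [0, 10),
  1-unit cells on [10, 60), one overflow cell — 71 RMSD cells.  Stage 1
  applies the same subdivision beyond contact (142 cells); stage 2 merges
  the non-contact side into one cell (72 cells), which under a fixed
  global walker count shifts most sampling effort onto rearrangements of
  contact configurations.  The stated spacings yield 71 contact-side
  cells, not a round 72; the package implements the spacings as stated.
* Cells are half-open `[lo, hi)`; a value exactly on an edge belongs to
  the upper cell; the final cell is open-ended.  Assignment is a
  deterministic `findInterval`, property-tested to partition the space.

`binding_rmsd()` superposes the frame on the receptor points by the Kabsch
algorithm (SVD, proper rotation enforced; collinear or coincident fit sets
are an error) and reports the RMSD over the ligand anchors.  For the toy
geometry the receptor frame *is* the laboratory frame, and the analytic
shortcut in `toy_pcoord()` is tested to agree with the generic Kabsch
route to 1e-9.

## Resampling policies

`per_bin_target` keeps `M` walkers per occupied bin.  `fixed_total` keeps
the global count fixed (the two-stage binding run uses it): each occupied
bin receives `max(1, floor(total/occupied))` slots and the remainder goes
one-by-one to the heaviest bins — this keeps coverage even while the
stage-2 bin merge automatically reallocates walkers toward the contact
region.  Open allocation choices were resolved as: merges always pair the
two lowest-weight walkers in the bin (survivor weight-proportional);
splits always halve the heaviest walker, ties broken by walker id; both
loops run until the target is met.  Weight conservation is exact because
halving and summing are exact in binary floating point.

The stage-1 → stage-2 switch can be triggered at a fixed iteration or
automatically once every initial-state lineage either has a descendant
that visited the encounter state or has died out (bracketed by
`switch_window`).  Switching never touches weights or dynamic states —
only bin assignments — and the next resampling adapts the counts.

## Uncertainty estimation

The blocked bootstrap works in two passes: (1) `flux_autocorr_tc()`
bootstraps the lag-ℓ autocorrelation of the per-iteration flux series by
resampling lag-ℓ *pairs* (resampling the raw series would destroy the lag
relation) and finds the largest lag whose 95% percentile interval excludes
zero; the block length is that lag **plus one** — values ℓ apart being
correlated means a decorrelating block must span ℓ + 1 values, so white
noise gives t_c = 1 and a perfectly duplicated series gives t_c = 2.
(2) `blocked_bootstrap_ci()` averages non-overlapping blocks of length
t_c (trailing partial block dropped, not wrapped) and reports the
percentile interval of the mean over 1000 resampled datasets.  Percentile
intervals, not BCa: the simplest faithful reading of "Monte Carlo blocked
bootstrapping".  Significance is per lag, without multiplicity
correction, so for white noise individual lags are falsely significant at
the nominal 5% rate; `max_lag` defaults to a tenth of the series length,
capped at 100.  The number of statistically independent binding events
reuses the same machinery on the per-iteration arrival counts (effective
count = total / t_c); the ratio CI for the productive-collision percentage
uses first-order (delta-method) propagation, relative variances adding in
quadrature.  Coverage of the 95% interval is verified by simulation
(500 iid replicates; observed ≈ 93–95%).

## Validation experiments and problem sizes

The `benchmark_*` functions are the package's validation suite; the same
functions back the test suite and `scripts/acceptance.R`.  Sizes are
scaled-down study conditions chosen to converge on one CPU in minutes:

* **Weight conservation** — 64 walkers, 500 iterations, two-dimensional
  binding scheme: max |1 − Σw| ≈ 1e-16.
* **Unbiasedness** — 1-D double well U = h(x² − 1)², h = 3 kT, D = 1,
  dt = 0.005, τ = 40 steps, 16 + 1 cells of width 0.3: WE equilibrium bin
  probabilities (3500 iterations, last 2000 averaged) against a 10⁷-step
  brute-force trajectory sampled every τ; both error bars from block
  averages with a 150-iteration block, several times the ~37-iteration
  population autocorrelation time (shorter blocks demonstrably
  underestimate the errors); agreement within 3σ in every populated cell
  (observed max z ≈ 1.3–2.4 across seeds).
* **Hill relation** — force-free ligand, absorbing sphere at separation 5,
  start/recycle at separation 20: recycling-mode WE flux (1500 iterations,
  last 800) against 1/T from `shell_mfpt_analytic()`.  Absorption is
  implemented *inside* the propagator (per-step check, `absorb_radius`):
  detecting absorption only at τ boundaries misses sub-τ crossings and
  displaces the effective boundary by ~0.8·√(2Dτ), which at this geometry
  would bias the flux ~17% low; per-step absorption at dt = 0.02 leaves a
  ~1% residual, small against the ±8% confidence interval.
* **Rate pipeline** — four independent two-stage binding runs (each 80
  initial pairs × 4 copies, fixed total 320, τ = 20, 400 + 400
  iterations; k1 from the last 100 stage-1 iterations, kon and k2 from
  the last 300 iterations), compared against brute-force estimates from
  200 independent recycled first-passage events (CIs by bootstrapping
  whole events).  The WE uncertainty is a Student-t interval across the
  replicas rather than a single run's blocked bootstrap: at this scale
  the bound-state flux is carried by a few heavy lineages whose weights
  decorrelate over hundreds of iterations — arrival *events* are
  plentiful and stationary, but the arriving *weight* fluctuates several-
  fold between 100-iteration stretches — so within-run error bars
  undercover badly, a known failure mode of aggressively scaled WE runs.
  This benchmark runs WE in *recycling* mode: at toy
  scale the binding MFPT is comparable to the run length, so the
  equilibrium-mode labelled decomposition retains a slowly decaying
  transient (the 10 kT bound state returns no B→U flux within the run)
  and its kon converges from below; recycling realizes exactly the
  stationary ensemble the brute-force process samples.  In the rare-event
  regime the equilibrium-mode decomposition and the recycling steady
  state coincide; equilibrium remains the package default.  The
  full-scale study conditions (100 × 16 = 1600 walkers, τ = 20 ps, 650
  iterations ≙ 13 ns molecular time) are preserved as the printed-constant
  checks and the documented full-scale configuration.
* **Closed forms** — histogram entropy R·ln k on uniform k-cell data
  (exact), Canberra worked values (exact), delta-method ratio CI √2 × 10%
  for two 10% inputs (exact).
* **K-centers** — greedy radius ≤ 2 × the exhaustive optimum on 100
  random instances with n ≤ 8, every seed point (observed worst ratio
  ≈ 1.74).

## Pathway analyses

`extract_tpe()` walks each binding-direction bound arrival (pre-entry
history label `U`) backwards through the stored parent links to the most
recent unbound frame; the transition path spans everything after that last
unbound exit up to the first bound frame, carries the arriving walker's
weight, and keeps a per-frame encounter flag — all frames between the
stable states are retained rather than encounter frames being excised,
with the flag allowing either convention downstream.  Paths from distinct
initial-state lineages are marked independent through the root index.
Event durations are weighted histograms of frames × τ.  Contact
probabilities are weight fractions of frames within a cutoff (default
4.5), with (receptor centre/patch point, ligand centre/anchor) pairs
standing in for residue pairs, so extending to real structures is a
matter of supplying a different distance table.  Conformation-space
networks cluster progress-coordinate feature vectors with greedy
k-centers under the Canberra metric (k = 50 at toy scale; deterministic
given the seed point) and record observed inter-cluster transitions as
directed weighted edges; any force-directed layout may render them — the
topology and node attributes are the tested artifact.  Spherical entry
maps use 30 equal-area latitude bands (uniform in cos θ) subdivided in
longitude into near-square cells, each annotated with its solid angle;
"30 bins" is read as 30 bands, recorded in the output.

## Numerical conventions and degenerate inputs

Weight tolerance 1e-12 per iteration (observed 1e-16); quaternion norm
tolerance 1e-9; Kabsch degeneracy threshold 1e-10 on the second singular
value; empty histogram cells contribute zero entropy and all-identical
samples give S = 0; Canberra 0/0 terms are 0; an empty transition path
ensemble is a value, not an error, while an empty duration histogram is an
error; zero-variance series are rejected by the autocorrelation routine
and handled as t_c = 1 by the event counter; volumes for
`effective_concentration()` are in nm³ (1 nm³ = 10⁻²⁴ L — note that a
volume printed in Å³ yielding a millimolar concentration must be read as
nm³).  Internal fluxes are per time unit of the propagator; conversions to
s⁻¹ and M⁻¹s⁻¹ happen only at reporting.

## Limitations

Sub-τ recrossings are invisible to all state bookkeeping; the toy model's
"residues" are four geometric points, so contact maps have four columns,
not a residue × residue matrix; the run store is an in-memory R object
(serialize with `saveRDS()` if needed); unbinding-direction kinetics
(k_off) are supported by the label machinery but no unbinding observable
is computed, since the sampling setup does not generate a meaningful
unbinding ensemble.
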